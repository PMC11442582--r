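#' Right-hand side of the liver-injury ODE system
#'
#' Evaluates the time derivative of the six-variable mass-action model at a
#' state. In the ordering `T, M1, M2, E, C, F` the equations are
#'
#' \deqn{dT/dt   = -K_T M_2 T - D T}
#' \deqn{dM_1/dt = B_1 T + E - \frac{G}{(C+1)(F+1)} M_1 - D M_1}
#' \deqn{dM_2/dt = B_2 T + \frac{G}{(C+1)(F+1)} M_1 - D M_2}
#' \deqn{dE/dt   = B_E (1+E) M_1 - D E}
#' \deqn{dC/dt   = B_C F - K_C M_2 C - D C}
#' \deqn{dF/dt   = B_F M_1 - K_F M_2 F - D F}
#'
#' Senescent cells recruit both macrophage phenotypes; activated endothelium
#' recruits M1 (the unit-rate `E` term fixes the time scale); the M1-to-M2
#' switch at rate `G` is damped by ECM and myofibroblast load; M1 activates
#' endothelium (with proliferation of the activated pool) and myofibroblasts;
#' myofibroblasts deposit ECM; M2 clears senescent cells, ECM and
#' myofibroblasts. Homeostasis (the zero state) is an exact fixed point.
#'
#' @param state numeric state vector of length 6 in the order
#'   `T, M1, M2, E, C, F` (named vectors are reordered by name).
#' @param params a [model_params()] object.
#' @return Named numeric vector of length 6: the derivative, same ordering.
#' @examples
#' rhs(c(1, 0, 0, 0, 0, 0), model_params())  # (-1, 1, 1, 0, 0, 0)
#' @export
rhs <- function(state, params) {
  state <- validate_state(state)
  params <- as_params(params)
  rhs_raw(state, params)
}

# Derivative closure for the integrator: parameters unpacked to scalars once,
# no names, no list access in the hot loop.
make_deriv <- function(p) {
  K_T <- p$K_T; D <- p$D; B1 <- p$B1; B2 <- p$B2; G <- p$G
  B_E <- p$B_E; B_C <- p$B_C; K_C <- p$K_C; B_F <- p$B_F; K_F <- p$K_F
  function(t, y, parms) {
    sw <- G / ((y[5L] + 1) * (y[6L] + 1))
    list(c(-K_T * y[3L] * y[1L] - D * y[1L],
           B1 * y[1L] + y[4L] - sw * y[2L] - D * y[2L],
           B2 * y[1L] + sw * y[2L] - D * y[3L],
           B_E * (1 + y[4L]) * y[2L] - D * y[4L],
           B_C * y[6L] - K_C * y[3L] * y[5L] - D * y[5L],
           B_F * y[2L] - K_F * y[3L] * y[6L] - D * y[6L]))
  }
}

# Hot path used by the integrator: no validation, positional access.
rhs_raw <- function(y, p) {
  Tt <- y[1L]; M1 <- y[2L]; M2 <- y[3L]; E <- y[4L]; C <- y[5L]; F <- y[6L]
  sw <- p$G / ((C + 1) * (F + 1)) # phenotype-switch rate, damped by scar load
  c(T  = -p$K_T * M2 * Tt - p$D * Tt,
    M1 = p$B1 * Tt + E - sw * M1 - p$D * M1,
    M2 = p$B2 * Tt + sw * M1 - p$D * M2,
    E  = p$B_E * (1 + E) * M1 - p$D * E,
    C  = p$B_C * F - p$K_C * M2 * C - p$D * C,
    F  = p$B_F * M1 - p$K_F * M2 * F - p$D * F)
}

#' Analytic Jacobian of the model
#'
#' Matrix of partial derivatives of [rhs()] with respect to the state,
#' computed in closed form (including the C- and F-derivatives of the
#' `(C+1)(F+1)` phenotype-switch divisor). Used for linear stability analysis
#' of steady states.
#'
#' @inheritParams rhs
#' @return 6 x 6 numeric matrix with rows and columns named
#'   `T, M1, M2, E, C, F`; entry (i, j) is the derivative of the i-th
#'   equation with respect to the j-th variable.
#' @seealso [stability()]
#' @export
jacobian <- function(state, params) {
  state <- validate_state(state)
  params <- as_params(params)
  jacobian_raw(state, params)
}

jacobian_raw <- function(y, p) {
  Tt <- y[1L]; M1 <- y[2L]; M2 <- y[3L]; E <- y[4L]; C <- y[5L]; F <- y[6L]
  sw <- p$G / ((C + 1) * (F + 1))
  J <- matrix(0, 6L, 6L, dimnames = list(STATE_VARS, STATE_VARS))
  J["T", "T"]   <- -p$K_T * M2 - p$D
  J["T", "M2"]  <- -p$K_T * Tt
  J["M1", "T"]  <- p$B1
  J["M1", "M1"] <- -sw - p$D
  J["M1", "E"]  <- 1
  J["M1", "C"]  <- sw * M1 / (C + 1)
  J["M1", "F"]  <- sw * M1 / (F + 1)
  J["M2", "T"]  <- p$B2
  J["M2", "M1"] <- sw
  J["M2", "M2"] <- -p$D
  J["M2", "C"]  <- -sw * M1 / (C + 1)
  J["M2", "F"]  <- -sw * M1 / (F + 1)
  J["E", "M1"]  <- p$B_E * (1 + E)
  J["E", "E"]   <- p$B_E * M1 - p$D
  J["C", "M2"]  <- -p$K_C * C
  J["C", "C"]   <- -p$K_C * M2 - p$D
  J["C", "F"]   <- p$B_C
  J["F", "M1"]  <- p$B_F
  J["F", "M2"]  <- -p$K_F * F
  J["F", "F"]   <- -p$K_F * M2 - p$D
  J
}
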