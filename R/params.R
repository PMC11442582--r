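#' Model state variables
#'
#' Canonical ordering of the six state variables. All are dimensionless
#' deviations from homeostasis: `T` senescent hepatocytes, `M1`
#' pro-inflammatory macrophages, `M2` pro-regenerative macrophages, `E`
#' activated endothelial cells (all normalised to the homeostatic endothelial
#' population), `C` extracellular-matrix concentration and `F` activated
#' myofibroblasts (each normalised to its own homeostatic level). Homeostasis
#' is the zero state.
#'
#' @export
STATE_VARS <- c("T", "M1", "M2", "E", "C", "F")

PARAM_NAMES <- c("K_T", "D", "B1", "B2", "G", "B_E", "B_C", "K_C", "B_F", "K_F")

#' Rate parameters of the liver-injury model
#'
#' Constructs and validates the ten nonnegative mass-action rate constants.
#' All rates default to 1, the reference parameter set used throughout the
#' model's published simulations.
#'
#' @param K_T rate of senescent-cell removal per pro-regenerative (M2)
#'   macrophage.
#' @param D death/deactivation rate, shared by all species; must be > 0.
#' @param B1 M1 recruitment rate per senescent cell.
#' @param B2 M2 recruitment rate per senescent cell.
#' @param G M1 to M2 phenotype-switch rate; the switch is damped by ECM and
#'   myofibroblast load through the factor 1/((C+1)(F+1)).
#' @param B_E endothelial activation rate per M1 cell.
#' @param B_C ECM deposition rate per myofibroblast.
#' @param K_C ECM breakdown rate per M2 cell.
#' @param B_F myofibroblast activation rate per M1 cell.
#' @param K_F myofibroblast deactivation rate per M2 cell.
#'
#' @return An object of class `senliver_params`: a named list of the ten
#'   rates with a logical `resolving_regime` attribute, `TRUE` iff
#'   `G > B_E - 1`, the condition under which the homeostatic state is
#'   linearly stable (for D = 1) so that sufficiently small injuries resolve.
#'   A warning (not an error) is raised outside that regime, since the model
#'   is still well-defined there and supercritical behaviour is of interest.
#' @seealso [initial_condition()], [rhs()], [regime()]
#' @examples
#' p <- model_params()              # reference all-ones parameter set
#' model_params(G = 2, B_E = 0.5)  # strongly resolving
#' @export
model_params <- function(K_T = 1, D = 1, B1 = 1, B2 = 1, G = 1,
                         B_E = 1, B_C = 1, K_C = 1, B_F = 1, K_F = 1) {
  p <- list(K_T = K_T, D = D, B1 = B1, B2 = B2, G = G,
            B_E = B_E, B_C = B_C, K_C = K_C, B_F = B_F, K_F = K_F)
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative (got ", v, ")", call. = FALSE)
  }
  if (p$D <= 0) stop("death/deactivation rate 'D' must be strictly positive",
                     call. = FALSE)
  resolving <- p$G > p$B_E - 1
  if (!resolving)
    warning("parameter set is outside the resolving regime (G <= B_E - 1): ",
            "homeostasis is linearly unstable and arbitrarily small injuries ",
            "fail to resolve", call. = FALSE)
  structure(p, resolving_regime = resolving, class = "senliver_params")
}

#' @export
print.senliver_params <- function(x, ...) {
  cat("Liver-injury model rate parameters:\n")
  print(unlist(x[PARAM_NAMES]))
  cat(if (isTRUE(attr(x, "resolving_regime")))
        "Regime: resolving (G > B_E - 1)\n"
      else "Regime: no-resolution (G <= B_E - 1)\n")
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "senliver_params")) return(params)
  if (is.list(params) || is.numeric(params))
    return(do.call(model_params, as.list(params)[PARAM_NAMES[PARAM_NAMES %in% names(params)]]))
  stop("'params' must be created by model_params()", call. = FALSE)
}

#' Initial condition of an injury simulation
#'
#' The injury protocol deposits an initial senescent-cell load `T_in` into an
#' otherwise homeostatic liver: the default state is
#' `(T_in, 0, 0, 0, 0, 0)` in the ordering `T, M1, M2, E, C, F`.
#'
#' @param T_in initial senescent-cell level (nonnegative); the dose analogue.
#' @param state optional full six-component nonnegative state override
#'   (named or in canonical order), mainly for testing.
#' @return An object of class `senliver_init` with elements `T_in` and
#'   `state` (named numeric of length 6).
#' @examples
#' initial_condition(1.4)  # the "Medium" dose
#' @export
initial_condition <- function(T_in = 1, state = NULL) {
  if (!is.numeric(T_in) || length(T_in) != 1L || !is.finite(T_in) || T_in < 0)
    stop("'T_in' must be a single finite nonnegative number", call. = FALSE)
  if (is.null(state)) {
    state <- c(T_in, 0, 0, 0, 0, 0)
  } else {
    state <- validate_state(state)
    if (any(state < 0))
      stop("initial state components must be nonnegative", call. = FALSE)
    T_in <- unname(state[1L])
  }
  names(state) <- STATE_VARS
  structure(list(T_in = T_in, state = state), class = "senliver_init")
}

as_init <- function(init) {
  if (inherits(init, "senliver_init")) return(init)
  if (is.numeric(init) && length(init) == 1L) return(initial_condition(init))
  if (is.numeric(init) && length(init) == 6L) return(initial_condition(state = init))
  stop("'init' must be an initial_condition(), a T_in value, or a 6-vector",
       call. = FALSE)
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 6L)
    stop("state must be a numeric vector of length 6 (T, M1, M2, E, C, F)",
         call. = FALSE)
  if (!is.null(names(state)) && all(STATE_VARS %in% names(state)))
    state <- state[STATE_VARS]
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state component(s): ",
         paste(STATE_VARS[bad], collapse = ", "), call. = FALSE)
  # The phenotype-switch divisor (C+1)(F+1) changes sign below -1; such states
  # are outside the model's domain and are rejected rather than evaluated.
  if (state[5L] < -1 || state[6L] < -1)
    stop("state components C and F must be > -1 (switch-term divisor)",
         call. = FALSE)
  stats::setNames(as.numeric(state), STATE_VARS)
}

#' Read / write parameter sets as JSON
#'
#' A parameter set (plus the initial senescence `T_in`) serialises to a flat
#' JSON object with keys `K_T, D, B1, B2, G, B_E, B_C, K_C, B_F, K_F, T_in`.
#' Unknown keys are rejected so that silently misspelled rates cannot slip
#' through a configuration file.
#'
#' @param path file path.
#' @param params a [model_params()] object.
#' @param init an [initial_condition()] object (its `T_in` is stored).
#' @return `read_params_json()` returns `list(params = , init = )`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- names(obj)
  allowed <- c(PARAM_NAMES, "T_in")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown key(s) in parameter JSON: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_params, obj[intersect(keys, PARAM_NAMES)])
  T_in <- if ("T_in" %in% keys) obj[["T_in"]] else 1
  list(params = params, init = initial_condition(T_in))
}

#' @rdname read_params_json
#' @export
write_params_json <- function(path, params, init = initial_condition(1)) {
  params <- as_params(params)
  init <- as_init(init)
  obj <- c(params[PARAM_NAMES], list(T_in = init$T_in))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
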