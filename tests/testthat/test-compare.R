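# Round-trip material shared across the checks below.
rt <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- model_params()
      des <- design_config(params = p, cv = 0.2, n_animals = 4L, seed = 11)
      map <- default_marker_map(p, des)
      d <- generate_dataset(p, map, des)
      val <<- list(params = p, design = des, map = map, data = d,
                   summaries = summarize_dataset(d),
                   pred = predict_markers(d),
                   config = list(cv = 0.2, n_control = 4L,
                                 dose_order = c("mild", "moderate", "severe")))
    }
    val
  }
})

test_that("model-generated data pass every evaluable qualitative check", {
  rep <- validate_dataset(rt()$data)
  expect_s3_class(rep, "senliver_validation")
  expect_true(attr(rep, "verdict"))
  expect_gt(sum(rep$evaluable), 50)
  expect_true(all(rep$pass[rep$evaluable]))
  # every check type appears, and each (check, marker, group) scope once
  expect_setequal(unique(rep$check),
                  c("transient", "resolution", "senescence_decline",
                    "codirection", "dose_ordering"))
  expect_false(any(duplicated(rep[, c("check", "marker", "group")])))
})

test_that("a senescence marker stuck high at the final day fails resolution", {
  s2 <- rt()$summaries
  sel <- s2$marker == "p21" & s2$day == 14
  s2$mean[sel] <- 50
  s2$sem[sel] <- 1
  rep <- qualitative_checks(s2, rt()$pred, config = rt()$config)
  expect_false(attr(rep, "verdict"))
  bad <- rep[!rep$pass & rep$evaluable, ]
  expect_true(all(bad$check == "resolution"))
  expect_true(all(bad$marker == "p21"))
})

test_that("an inverted dose ordering at the peak day is caught", {
  s2 <- rt()$summaries
  pred <- rt()$pred
  sev <- pred[pred$marker == "CD80" & pred$group == "severe", ]
  d_peak <- sev$day[which.max(sev$expected)]
  hi <- s2$mean[s2$marker == "CD80" & s2$day == d_peak &
                  s2$group == "severe"]
  s2$mean[s2$marker == "CD80" & s2$day == d_peak & s2$group == "mild"] <-
    hi * 2
  rep <- qualitative_checks(s2, pred, config = rt()$config)
  bad <- rep[!rep$pass & rep$evaluable, ]
  expect_true(any(bad$check == "dose_ordering" & bad$marker == "CD80"))
})

test_that("validation reports are deterministic in their inputs", {
  r1 <- qualitative_checks(rt()$summaries, rt()$pred, config = rt()$config)
  r2 <- qualitative_checks(rt()$summaries, rt()$pred, config = rt()$config)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("moderate-noise data pass the full check battery in >= 95% of seeds", {
  p <- rt()$params
  map <- rt()$map
  trajs <- attr(rt()$data, "trajectories")
  ts <- rt()$design$timescale
  passes <- vapply(1:100, function(s) {
    des <- design_config(params = p, cv = 0.2, n_animals = 5L, seed = s,
                         timescale = ts)
    d <- generate_dataset(p, map, des, trajectories = trajs)
    attr(validate_dataset(d), "verdict")
  }, logical(1))
  expect_gte(sum(passes), 95L)
})

test_that("validation reports serialise to JSON and text", {
  rep <- validate_dataset(rt()$data)
  path <- tempfile(fileext = ".json")
  write_validation_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(back$verdict)
  expect_equal(nrow(back$checks), nrow(rep))
  expect_true(file.exists(sub("\\.json$", ".txt", path)))
})
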