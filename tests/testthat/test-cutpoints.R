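test_that("the built-in registry holds exactly the published thresholds", {
  expected <- list(
    list("pate", "vertical", 800, 1680),
    list("butte", "vertical", 239, 2120),
    list("johansson", "vertical", 580, 3480),
    list("butte", "vector_magnitude", 820, 1908),
    list("johansson", "vector_magnitude", 2136, 6144))
  for (e in expected) {
    s <- get_cutpoint_set(e[[1]], e[[2]])
    expect_equal(s$sb_upper_cpm, e[[3]])
    expect_equal(s$mvpa_lower_cpm, e[[4]])
  }
  expect_setequal(builtin_cutpoint_names("vertical"),
                  c("pate", "butte", "johansson"))
  expect_setequal(builtin_cutpoint_names("vector_magnitude"),
                  c("butte", "johansson"))
  expect_error(get_cutpoint_set("pate", "vector_magnitude"),
               "not defined on the vector magnitude")
})

test_that("built-in sets cannot be silently overridden, custom sets can add", {
  expect_error(cutpoint_set("pate", "vertical", 700, 1500),
               "cannot be overridden")
  custom <- cutpoint_set("evenson", "vertical", 100, 2296)
  expect_s3_class(get_cutpoint_set("evenson", "vertical",
                                   extra = list(custom)), "cutpoint_set")
  expect_error(cutpoint_set("x", "vertical", 2000, 1000), "below")
})

test_that("cpm thresholds rescale exactly to the analysis epoch", {
  pate <- get_cutpoint_set("pate", "vertical")
  expect_equal(epoch_thresholds(pate, 5),
               c(sb_upper = 800 / 12, mvpa_lower = 140))
  expect_equal(epoch_thresholds(get_cutpoint_set("butte", "vertical"), 5),
               c(sb_upper = 239 / 12, mvpa_lower = 2120 / 12))
  expect_equal(epoch_thresholds(pate, 60),
               c(sb_upper = 800, mvpa_lower = 1680))
})

test_that("boundary convention: < sedentary bound, >= MVPA bound", {
  pate <- get_cutpoint_set("pate", "vertical")
  expect_equal(as.character(classify_epoch(c(799, 800, 1679, 1680), pate, 60)),
               c("sedentary", "light", "light", "mvpa"))
  # exact rational boundaries at 5 s: 800/12 = 66.67 counts per epoch
  expect_equal(as.character(classify_epoch(c(66, 67, 139, 140), pate, 5)),
               c("sedentary", "light", "light", "mvpa"))
  expect_error(classify_epoch(-1, pate, 60), "non-negative")
})

test_that("series labelling matches per-epoch brute force and honours wear", {
  set.seed(5)
  s <- random_series(5000, max_count = 400)
  worn <- wear_mask(s, detect_nonwear(s))
  for (nm in c("pate", "butte", "johansson")) {
    set <- get_cutpoint_set(nm, "vertical")
    lab <- classify_series(s, set, worn)
    expect_identical(as.character(lab[worn]),
                     bf_classify(s$counts[worn, 1], set, 5))
    expect_true(all(is.na(lab[!worn])))
    expect_false(anyNA(lab[worn]))  # exhaustive + exclusive on worn epochs
  }
  # all-zero worn epochs are sedentary
  z <- make_series(integer(100))
  expect_true(all(classify_series(z, get_cutpoint_set("pate")) == "sedentary"))
})

test_that("threshold ordering induces MVPA/SB ordering on shared input", {
  set.seed(6)
  for (i in 1:5) {
    s <- random_series(3000, max_count = 350, zero_prob = 0.2)
    labs <- lapply(c("pate", "butte", "johansson"), function(nm)
      classify_series(s, get_cutpoint_set(nm, "vertical")))
    mvpa <- vapply(labs, function(l) sum(l == "mvpa"), numeric(1))
    sb <- vapply(labs, function(l) sum(l == "sedentary"), numeric(1))
    expect_true(mvpa[1] >= mvpa[2] && mvpa[2] >= mvpa[3])  # 1680<2120<3480
    expect_true(sb[2] <= sb[3] && sb[3] <= sb[1])          # 239<580<800
  }
})
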