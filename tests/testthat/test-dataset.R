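# Manifest construction, composition arithmetic and row regeneration.

test_that("default selection composition matches the reference totals", {
  man <- build_selection_dataset(selection_config(), render = FALSE)
  comp <- attr(man, "composition")
  expect_equal(nrow(man), 1799L)
  expect_equal(unname(comp[c("turing", "kt", "gray_scott",
                             "edwards_wilkinson", "eden", "dla",
                             "l_system", "phase_field")]),
               c(228L, 288L, 486L, 99L, 182L, 300L, 133L, 83L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(man$path) > 0)
})

test_that("empty and custom selection configs", {
  man0 <- build_selection_dataset(selection_config(counts = c(turing = 0L)),
                                  render = FALSE)
  expect_equal(nrow(man0), 0L)
  man5 <- build_selection_dataset(selection_config(counts = c(turing = 5L)),
                                  render = FALSE)
  expect_equal(nrow(man5), 5L)
  expect_true(all(man5$model == "turing"))
  expect_equal(length(unique(man5$param_json)), 5L)
})

test_that("manifest rows regenerate their images byte-for-byte", {
  cfg <- selection_config(counts = c(kt = 2L, eden = 2L, l_system = 2L),
                          size = 32L, fast = TRUE)
  dir <- tempfile("regen")
  man <- build_selection_dataset(cfg, out_dir = dir, seed = 7L,
                                 render = TRUE)
  for (i in seq_len(nrow(man))) {
    img <- regenerate_row(man, i)
    f2 <- tempfile(fileext = ".png")
    write_image(if (max(img) > 1) normalize_field(img) else img, f2)
    expect_identical(readBin(man$path[i], "raw", 1e6),
                     readBin(f2, "raw", 1e6))
  }
})

test_that("estimation manifest: counts, box membership, split flags", {
  man <- build_estimation_dataset(seed = 3L)
  expect_equal(sum(man$split == "train"), 9700L)
  expect_equal(sum(man$split == "val"), 600L)
  expect_true(all(man$f_v >= 0.6 & man$f_v <= 1.0))
  expect_true(all(man$g_v >= 0.6 & man$g_v <= 1.0))
  man2 <- build_estimation_dataset(n_train = 0L, n_val = 10L, seed = 3L)
  expect_true(all(man2$split == "val"))
  expect_error(build_estimation_dataset(box = c(1.8, 2.4), seed = 1L),
               "simulator-valid")
})

test_that("manifest CSV round trip preserves rows and composition", {
  man <- build_estimation_dataset(n_train = 20L, n_val = 5L, seed = 2L)
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(nrow(back), 25L)
  expect_equal(back$f_v, man$f_v, tolerance = 1e-12)
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(side$total, 25L)
  expect_equal(side$composition$turing, 25L)
})
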