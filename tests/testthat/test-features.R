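zero_thresh_params <- feature_params(wamp_threshold = 0, myop_threshold = 0)

test_that("constant segments give their closed-form feature values", {
  for (c0 in c(0.5, 2, 7.25)) {
    L <- 64
    x <- rep(c0, L)
    f <- time_features(x)
    expect_equal(unname(f["mav"]), c0)
    expect_equal(unname(f["rms"]), c0)
    expect_equal(unname(f["log_detector"]), c0)
    expect_equal(unname(f[c("wl", "aac", "zc", "ssc", "wamp", "dasdv")]),
                 rep(0, 6))
    expect_equal(unname(f["var"]), c0^2 * L / (L - 1))
    expect_equal(unname(f["ssi"]), L * c0^2)
    expect_equal(sample_entropy(x), 0)
    expect_equal(approximate_entropy(x), 0)
    expect_equal(fuzzy_entropy(x), 0)
    expect_equal(shannon_entropy(x, 16), 0)
    expect_equal(katz_fd(x), 1)
  }
})

test_that("the alternating signal matches hand arithmetic", {
  x <- rep(c(1, -1), 4)                      # L = 8
  f <- time_features(x, zero_thresh_params)
  expect_equal(unname(f["zc"]), 7)
  expect_equal(unname(f["wl"]), 14)
  expect_equal(unname(f["rms"]), 1)
  expect_equal(unname(f["dasdv"]), 2)        # sqrt(4 * 7 / 7)
  expect_equal(unname(f["mav"]), 1)
  expect_equal(unname(f["ssi"]), 8)
})

test_that("sinusoid features: two sign crossings and rms near 1/sqrt(2)", {
  t <- (0:999) / 1000
  x <- sin(2 * pi * t + 0.1)                 # phase offset avoids exact zeros
  f <- time_features(x)
  expect_equal(unname(f["zc"]), 2)
  expect_equal(unname(f["rms"]), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(unname(f["ssc"]), 2)          # one maximum, one minimum
})

test_that("ramps are maximally regular: zero entropy patterns, unit fractal dimension", {
  x <- as.numeric(1:100)
  f <- time_features(x)
  expect_equal(unname(f["wl"]), 99)
  expect_equal(unname(f["aac"]), 0.99)
  expect_equal(unname(f["zc"]), 0)
  expect_equal(unname(f["ssc"]), 0)
  expect_equal(unname(f["mfl"]), log10(sqrt(99)))
  expect_equal(permutation_entropy(x, 3, 1), 0)
  expect_equal(katz_fd(x), 1)
  expect_equal(higuchi_fd(x, kmax = 8), 1, tolerance = 0.05)
})

test_that("features obey their scale and shift laws", {
  set.seed(7)
  p <- feature_params()
  linear_scale <- c("mav", "rms", "wl", "aac", "dasdv", "log_detector")
  quad_scale <- c("var", "ssi")
  scale_free <- c("zc", "ssc", "myop", "wamp")
  shift_free <- c("wl", "aac", "dasdv", "ssc", "mfl")
  for (i in 1:10) {
    x <- rnorm(150) + 0.5 * sin(seq(0, 10, length.out = 150))
    cs <- runif(1, 0.5, 5)
    f1 <- time_features(x, p)
    f2 <- time_features(cs * x, p)
    expect_equal(f2[linear_scale], cs * f1[linear_scale], tolerance = 1e-9)
    expect_equal(f2[quad_scale], cs^2 * f1[quad_scale], tolerance = 1e-9)
    expect_equal(f2[scale_free], f1[scale_free])
    f3 <- time_features(x + 3.2, p)
    expect_equal(f3[shift_free], f1[shift_free], tolerance = 1e-9)
    # SD-relative tolerances make the entropies scale-invariant
    expect_equal(sample_entropy(cs * x), sample_entropy(x), tolerance = 1e-9)
    expect_equal(approximate_entropy(cs * x), approximate_entropy(x),
                 tolerance = 1e-9)
    expect_equal(fuzzy_entropy(cs * x), fuzzy_entropy(x), tolerance = 1e-9)
    expect_equal(permutation_entropy(cs * x), permutation_entropy(x))
    expect_equal(katz_fd(cs * x), katz_fd(x), tolerance = 1e-9)
    expect_equal(higuchi_fd(x + 3.2), higuchi_fd(x), tolerance = 1e-9)
    expect_equal(permutation_entropy(x + 3.2), permutation_entropy(x))
    # structural invariants
    expect_equal(f1[["rms"]]^2 * 150, f1[["ssi"]], tolerance = 1e-9)
    expect_gte(f1[["myop"]], 0); expect_lte(f1[["myop"]], 1)
    expect_gte(sample_entropy(x), 0)
    expect_gte(katz_fd(x), 1)
  }
})

test_that("entropies order regular below irregular signals", {
  set.seed(3)
  square <- rep(c(1, 1, 1, -1, -1, -1), length.out = 300)
  noise <- rnorm(300)
  expect_lt(sample_entropy(square), sample_entropy(noise))
  expect_lt(approximate_entropy(square), approximate_entropy(noise))
  sine <- sin(2 * pi * (1:500) / 50)
  noise500 <- rnorm(500)
  expect_gt(sample_entropy(noise500), sample_entropy(sine))
})

test_that("optimized entropy/fractal estimators match their naive oracles", {
  set.seed(19)
  for (i in 1:5) {
    L <- sample(100:250, 1)
    x <- rnorm(L) + sin(seq(0, 6, length.out = L))
    expect_equal(sample_entropy(x, 2, 0.2), sampen_naive(x, 2, 0.2),
                 tolerance = 1e-10)
    expect_equal(approximate_entropy(x, 2, 0.2), apen_naive(x, 2, 0.2),
                 tolerance = 1e-10)
    expect_equal(permutation_entropy(x, 3, 1), permen_naive(x, 3, 1),
                 tolerance = 1e-10)
    expect_equal(higuchi_fd(x, 10), higuchi_naive(x, 10), tolerance = 1e-10)
  }
})

test_that("fuzzy entropy implements the membership-entropy form", {
  expect_equal(fuzzy_entropy(mu = rep(0.5, 20)), log(2))
  expect_equal(fuzzy_entropy(mu = rep(c(0, 1), 10)), 0)
  set.seed(23)
  x <- rnorm(200)
  ax <- abs(x)
  mu <- (ax - min(ax)) / (max(ax) - min(ax))
  expect_equal(fuzzy_entropy(x), fuzzyen_naive(mu), tolerance = 1e-12)
})

test_that("Shannon entropy of k equally-filled bins is log k", {
  x <- rep(as.numeric(1:8), each = 25)
  expect_equal(shannon_entropy(x, bins = 8), log(8))
  expect_equal(shannon_entropy(rep(c(0, 1), 50), bins = 4), log(2))
})

test_that("permutation entropy of iid noise approaches log(order!)", {
  set.seed(4)
  x <- rnorm(10000)
  expect_equal(permutation_entropy(x, 3, 1), log(6), tolerance = 0.05)
})

test_that("extract_features assembles all 24 values compositionally", {
  cfg <- synth_config(seed = 6, duration = 20)
  segs <- preprocess_pipeline(generate_record(cfg)$record)
  x <- segs[[1]]$x
  p <- feature_params()
  fv <- extract_features(segs[[1]], p)
  expect_identical(names(fv), ppg_feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(segs[[1]], p))  # deterministic
  expect_equal(unname(fv[1:17]), unname(time_features(x, p)))
  expect_equal(unname(fv["sampen"]), sample_entropy(x, p$sampen_m, p$sampen_r))
  expect_equal(unname(fv["shannon"]), shannon_entropy(x, p$shannon_bins))
  expect_equal(unname(fv["katz_fd"]), katz_fd(x))
  expect_error(extract_features(c(1, NA, 3)), "non-finite")
})

test_that("degenerate inputs follow the documented conventions", {
  x <- c(0, 1, 0, -2, 5, 0, 3, -1, 2, 0, 1, -1)
  f <- time_features(x)                       # exact zeros in log detector
  expect_true(is.finite(f[["log_detector"]]))
  expect_equal(katz_fd(rep(2, 50)), 1)        # zero path length -> line
  expect_equal(permutation_entropy(rep(1, 50), 3, 1), 0)  # ties by index
  # SampEn with no (m+1)-matches stays finite via the log(B+1) cap
  y <- c(0, 1e3, -2e3, 4e3, -8e3, 1.6e4, -3.2e4, 6.4e4, -1.28e5, 2.56e5)
  expect_true(is.finite(sample_entropy(y, 2, 0.01)))
})
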