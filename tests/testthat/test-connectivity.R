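# Symbolic transform, wSMI (against an independent joint-histogram
# oracle), PLV, ROI aggregation.

# independent wSMI oracle: explicit rank patterns via order(), explicit
# 6x6 contingency table, explicit identical/opposite weighting
wsmi_oracle <- function(x, y, tau) {
  sym <- function(v) {
    m <- length(v) - 2 * tau
    vapply(seq_len(m), function(t) {
      trip <- c(v[t], v[t + tau], v[t + 2 * tau])
      # earlier-index-smaller tie-break: stable order()
      paste(order(trip), collapse = "")
    }, "")
  }
  patterns <- c("123", "132", "213", "231", "312", "321")
  opposite <- function(p) paste(rev(strsplit(p, "")[[1]]), collapse = "")
  sx <- factor(sym(x), levels = patterns)
  sy <- factor(sym(y), levels = patterns)
  joint <- table(sx, sy) / length(sx)
  px <- rowSums(joint); py <- colSums(joint)
  tot <- 0
  for (i in patterns) for (j in patterns) {
    if (i == j || j == opposite(i)) next
    p <- joint[i, j]
    if (p > 0) tot <- tot + p * log(p / (px[i] * py[j]))
  }
  as.numeric(tot) / log(6)
}

test_that("symbolic transform enumerates rank patterns correctly", {
  expect_true(all(symbolic_transform(1:10, tau = 1) == 1))
  expect_true(all(symbolic_transform(10:1, tau = 1) == 6))
  # hand enumeration for x = (3,1,2,5,4,0), tau = 1: rank vectors are
  # (3,1,2)->id 5, (1,2,3)->id 1, (1,3,2)->id 2, (3,2,1)->id 6
  s <- symbolic_transform(c(3, 1, 2, 5, 4, 0), tau = 1)
  expect_length(s, 4)
  expect_equal(as.integer(s), c(5, 1, 2, 6))
  # ties break earlier-index-smaller: (1,1,2) -> ranks (1,2,3)
  expect_equal(as.integer(symbolic_transform(c(1, 1, 2), tau = 1)), 1L)
  # (2,2,1): ranks (2,3,1) -> id 4
  expect_equal(as.integer(symbolic_transform(c(2, 2, 1), tau = 1)), 4L)
  expect_error(symbolic_transform(1:4, tau = 2), "too short")
  expect_length(symbolic_transform(rnorm(100), tau = 7), 100 - 14)
})

test_that("wSMI vanishes for identical and sign-flipped series", {
  set.seed(21)
  x <- rnorm(300)
  expect_identical(wsmi(x, x, tau = 2), 0)
  expect_identical(wsmi(x, -x, tau = 2), 0)
})

test_that("wSMI equals the brute-force joint-histogram oracle", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(50:2000, 1)
    tau <- sample(1:5, 1)
    x <- rnorm(n)
    y <- 0.6 * x + 0.4 * rnorm(n)         # coupled pair
    expect_equal(wsmi(x, y, tau = tau), wsmi_oracle(x, y, tau),
                 tolerance = 1e-12)
  }
})

test_that("wSMI is invariant under strictly monotone transforms", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(400); y <- 0.5 * x + 0.5 * rnorm(400)
    v <- wsmi(x, y, tau = 3)
    expect_equal(wsmi(exp(x), y^3 + 2 * y, tau = 3), v, tolerance = 1e-12)
  }
})

test_that("PLV analytic limits hold", {
  fs <- 250
  set.seed(24)
  x <- as.numeric(mindstate:::band_filter(rnorm(5000), default_bands("alpha"), fs))
  expect_equal(plv(x, x, "alpha", fs), 1, tolerance = 1e-9)
  # constant quarter-cycle lag on a narrowband tone keeps phases locked
  t <- seq_len(5000) / fs
  s10 <- sin(2 * pi * 10 * t)
  s10_lag <- sin(2 * pi * 10 * (t - 0.025))
  expect_gt(plv(s10, s10_lag, "alpha", fs), 0.99)
  # independent broadband noise decorrelates (phases from the raw
  # analytic signal; narrow filtering would shrink the effective n)
  broad <- data.frame(name = "broad", f_lo = 1, f_hi = 45)
  expect_lt(plv(rnorm(10000), rnorm(10000), broad, fs), 0.05)
  # amplitude scaling invariance
  set.seed(25)
  a <- rnorm(3000); b <- rnorm(3000)
  expect_equal(plv(a, b, "alpha", fs), plv(5 * a, 0.1 * b, "alpha", fs),
               tolerance = 1e-9)
  expect_true(is.na(plv(rep(0, 100), rnorm(100), "alpha", fs)))
})

test_that("band wSMI on independent noise is near zero, symmetric, zero-diagonal", {
  set.seed(26)
  data <- array(rnorm(10 * 4 * 2500), c(10, 4, 2500))
  ep <- mindstate:::new_epoch_set(data, 250, c(0, 10),
                                  data.frame(trial_id = paste0("t", 1:10)))
  cr <- band_wsmi(ep, "alpha")
  off <- apply(cr$matrices, 1, function(m) m[upper.tri(m)])
  expect_lt(mean(off), 0.01)
  for (i in 1:10) {
    m <- cr$matrices[i, , ]
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
})

test_that("planted nonlinear coupling raises wSMI far above the null", {
  set.seed(27)
  fs <- 250; n <- 2500
  mk_trial <- function(couple) {
    s <- mindstate:::spectral_noise(n, fs, 8, 12)
    lag <- 6
    x <- rnorm(n) + if (couple) 2 * s else 0
    y <- rnorm(n) + if (couple)
      2 * mindstate:::cubic_distort(c(rep(0, lag), s[seq_len(n - lag)])) else 0
    c(wsmi(mindstate:::band_filter(x, default_bands("alpha"), fs),
           mindstate:::band_filter(y, default_bands("alpha"), fs),
           tau = tau_for_band("alpha", fs)))
  }
  null <- replicate(20, mk_trial(FALSE))
  coupled <- mean(replicate(5, mk_trial(TRUE)))
  expect_gt(coupled, mean(null) + 5 * sd(null))
})

test_that("ROI aggregation: 45 pairs, identity and block-constant cases", {
  sch <- roi_scheme(68)
  expect_length(sch$roi_names, 10)
  expect_equal(length(sch$assignment), 68)
  expect_true(all(table(sch$assignment) > 0))
  m <- matrix(rnorm(68 * 68), 68, 68)
  m <- (m + t(m)) / 2
  roi <- roi_aggregate(m, sch)
  expect_equal(dim(roi), c(10, 10))
  expect_equal(roi, t(roi))
  expect_equal(nrow(roi_pairs_long(roi)), 45)
  # one source per ROI: aggregation is the identity on pair values
  sch1 <- roi_scheme(10)
  expect_equal(as.integer(table(sch1$assignment)), rep(1L, 10))
  m1 <- matrix(rnorm(100), 10, 10); m1 <- (m1 + t(m1)) / 2
  roi1 <- roi_aggregate(m1, sch1)
  expect_equal(unname(roi1[upper.tri(roi1)]), m1[upper.tri(m1)])
  # block-constant source matrix maps to those constants
  mc <- matrix(0, 68, 68)
  for (i in 1:10) for (j in 1:10) {
    si <- which(sch$assignment == i); sj <- which(sch$assignment == j)
    mc[si, sj] <- i + j
  }
  roic <- roi_aggregate(mc, sch)
  expect_equal(unname(roic[2, 5]), 7)
  expect_error(roi_aggregate(matrix(0, 10, 10), sch), "matches|n_sources|==")
})

test_that("dissociation contrasts are antisymmetric and centered under the null", {
  rec_mb <- state_session("MB", seed = 301)
  rec_on <- state_session("ON", seed = 303)
  pre <- function(r) epoch_preprobe(r)
  # stack MB and ON pre-probe epochs into one labeled set
  em <- pre(rec_mb); eo <- pre(rec_on)
  data <- array(NA_real_, c(n_epochs(em) + n_epochs(eo), 32, dim(em$data)[3]))
  data[seq_len(n_epochs(em)), , ] <- em$data
  data[n_epochs(em) + seq_len(n_epochs(eo)), , ] <- eo$data
  md <- rbind(em$metadata, eo$metadata)
  md$trial_id <- paste0("t", seq_len(nrow(md)))
  ep <- mindstate:::new_epoch_set(data, em$fs, em$window, md)
  pairs <- planted_pairs(rec_mb$channels)
  ab <- plv_wsmi_dissociation_check(ep, "alpha", pairs,
                                    state_pairs = list(c("MB", "ON")))
  ba <- plv_wsmi_dissociation_check(ep, "alpha", pairs,
                                    state_pairs = list(c("ON", "MB")))
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
  # planted MB profile: phase locking up, information sharing down
  expect_gt(mean(ab$delta[ab$metric == "plv"]), 0)
  expect_lt(mean(ab$delta[ab$metric == "wsmi"]), 0)
})
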