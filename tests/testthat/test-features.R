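test_that("time-domain moments match hand computations", {
  seg <- make_segment(rbind(rep(3, 10), rep(c(1, -1), 5)), band = NA)
  expect_warning(td <- time_domain_features(seg), "constant")
  expect_equal(td$mav[1], 3)
  expect_equal(td$sd[1], 0)
  expect_equal(td$skewness[1], 0)
  expect_equal(td$mav[2], 1)
  expect_equal(td$sd[2], sqrt(10 / 9))   # n-1 denominator
  expect_equal(td$skewness[2], 0)
  expect_equal(td$kurtosis[2], -2)       # two-point symmetric: excess -2
  withr::with_seed(3, {
    sym <- sin(2 * pi * 5 * (0:999) / 250)
    td2 <- time_domain_features(make_segment(rbind(sym), band = NA))
  })
  expect_lt(abs(td2$skewness), 1e-10)
  expect_error(time_domain_features(make_segment(matrix(1, 1, 3),
                                                 band = NA)), "4 samples")
})

test_that("band power integrates to the sinusoid's A^2/2", {
  tt <- (0:1999) / 250
  seg <- make_segment(rbind(2 * sin(2 * pi * 35 * tt),
                            sin(2 * pi * 10 * tt),
                            4 * sin(2 * pi * 35 * tt)), band = "gamma")
  bp <- band_power(seg)
  expect_equal(bp[1], 2, tolerance = 0.2)        # A=2 -> 2
  expect_lt(bp[2], 0.02)                         # out-of-band tone
  expect_equal(bp[3] / bp[1], 4, tolerance = 0.05)  # quadratic scaling
})

test_that("local network features match known graphs", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  nf <- local_network_features(k3)
  expect_equal(nf$clustering_coeff, rep(1, 3))
  expect_equal(nf$betweenness, rep(0, 3))
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1
  path <- path + t(path)
  nfp <- local_network_features(path)
  expect_equal(nfp$betweenness, c(0, 1, 0))
  expect_equal(nfp$clustering_coeff, rep(0, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  nfs <- local_network_features(star)
  expect_equal(nfs$betweenness[1], 1)
  expect_equal(nfs$clustering_coeff, rep(0, 4))
  iso <- matrix(0, 2, 2)
  nfi <- local_network_features(iso)
  expect_equal(unlist(nfi), rep(0, 4), ignore_attr = TRUE)
})

test_that("higher-order vector responds to planted cycles and ignores labels", {
  flat <- matrix(1, 6, 6); diag(flat) <- 0
  ho_flat <- higher_order_vector(eegtopo:::connectivity_matrix(1 - flat,
                                                               "plv") |>
                                   distance_matrix())
  expect_equal(ho_flat[["PersistenceEntropy_1"]], 0)
  expect_equal(ho_flat[["BettiAmp_H1"]], 0)
  d_ring <- ring_distance(6, 1:4)
  dm <- structure(list(values = d_ring, metric = "plv"),
                  class = "distance_matrix")
  ho_ring <- higher_order_vector(dm)
  expect_gt(ho_ring[["BettiAmp_H1"]], 0)
  expect_gt(ho_ring[["LandAmp_H1_N1"]], 0)
  # node relabeling leaves every descriptor unchanged
  perm <- c(3, 6, 1, 5, 2, 4)
  dmp <- dm; dmp$values <- d_ring[perm, perm]
  expect_equal(higher_order_vector(dmp), ho_ring)
  # H1 output identical whether or not H2 is computed and discarded
  expect_equal(higher_order_vector(dm, max_dim = 2), ho_ring)
})

test_that("mutual information ranks dependence sensibly", {
  withr::with_seed(10, {
    n <- 120
    labels <- rep(c("mild", "moderate"), each = n / 2)
    indicator <- as.numeric(labels == "moderate")
    noise <- rnorm(n)
    x <- cbind(ind = indicator, noise = noise, noise_dup = noise)
  })
  mi <- mutual_information_scores(x, labels)
  expect_equal(mi[["ind"]], log(2), tolerance = 0.1)  # H(label), nats
  expect_lt(mi[["noise"]], 0.08)
  expect_equal(mi[["noise"]], mi[["noise_dup"]])
  expect_true(all(mi >= 0))
  expect_error(mutual_information_scores(x, rep("mild", n)), "2 classes")
})

test_that("feature selection policies return the documented sets", {
  sel <- select_features(policy = "paper_fixed")
  expect_length(sel, 11)
  expect_length(intersect(sel, eegtopo:::HIGHER_ORDER_NAMES), 7)
  expect_true(all(c("mav", "sd", "band_power", "betweenness") %in% sel))
  expect_false(any(c("skewness", "kurtosis", "clustering_coeff",
                     "PersistenceEntropy_1") %in% sel))
  mi <- stats::setNames(seq_along(eegtopo:::CANDIDATE_FEATURES) / 15,
                        eegtopo:::CANDIDATE_FEATURES)
  all15 <- select_features(policy = "mi_threshold", mi = mi, cutoff = 0)
  expect_length(all15, 15)
  top <- select_features(policy = "mi_threshold", mi = mi, cutoff = 0.9)
  expect_true(length(top) < 15)
  expect_error(select_features(policy = "mi_threshold"), "MI scores")
})

test_that("normalization uses frozen training statistics only", {
  tr <- toy_samples(n_per_class = 4, seed = 2)
  te <- toy_samples(n_per_class = 4, seed = 3)
  norm_tr <- normalize_features(tr)
  stacked <- do.call(rbind, lapply(norm_tr, `[[`, "features"))
  expect_equal(colMeans(stacked), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(stacked, 2, sd), rep(1, 3), ignore_attr = TRUE)
  norm_te <- normalize_features(tr, te)
  expect_identical(attr(norm_te, "center"), attr(norm_tr, "center"))
  # scaling a held-out value reproduces (x - mean_train) / sd_train
  ctr <- attr(norm_tr, "center"); scl <- attr(norm_tr, "scale")
  expect_equal(norm_te[[1]]$features[1, 1],
               (te[[1]]$features[1, 1] - ctr[1]) / scl[1])
  const <- tr
  const[[1]]$features[, 2] <- 7
  for (i in seq_along(const)) const[[i]]$features[, 2] <- 7
  expect_warning(normalize_features(const), "zero-variance")
})

test_that("smote balances classes by convex interpolation", {
  samples <- toy_samples(n_per_class = 12, seed = 4)
  # drop half the moderate class to create imbalance
  labs <- vapply(samples, `[[`, "", "label")
  imb <- c(samples[labs == "mild"], samples[labs == "moderate"][1:6])
  out <- smote_oversample(imb, k = 3, seed = 42)
  labs2 <- vapply(out, `[[`, "", "label")
  expect_equal(sum(labs2 == "mild"), sum(labs2 == "moderate"))
  syn <- out[vapply(out, `[[`, "", "origin") == "smote"]
  expect_length(syn, 6)
  expect_true(all(as.numeric(vapply(syn, `[[`, "", "subject_id")) > 50))
  # convexity: synthetic values within the minority feature range
  minority <- imb[vapply(imb, `[[`, "", "label") == "moderate"]
  rng <- range(vapply(minority, function(s) range(s$features),
                      numeric(2)))
  for (s in syn)
    expect_true(all(s$features >= rng[1] - 1e-9 &
                      s$features <= rng[2] + 1e-9))
  # determinism and no-op on balanced input
  out2 <- smote_oversample(imb, k = 3, seed = 42)
  expect_equal(out[[length(out)]]$features, out2[[length(out2)]]$features)
  expect_identical(smote_oversample(samples), samples)
  expect_warning(smote_oversample(c(samples[labs == "mild"],
                                    samples[labs == "moderate"][1:3]),
                                  k = 5, seed = 1), "reducing k")
})

test_that("one-dimensional smote stays in the minority interval", {
  mk <- function(v, lab, id) structure(
    list(features = matrix(v, 1, 1, dimnames = list(NULL, "f")),
         adjacency = matrix(0, 1, 1), label = lab,
         subject_id = id, band = "gamma", origin = "real"),
    class = "graph_sample")
  samples <- c(lapply(1:6, function(i) mk(rnorm(1, 10), "mild",
                                          as.character(i))),
               list(mk(0, "moderate", "7"), mk(1, "moderate", "8")))
  out <- smote_oversample(samples, k = 5, seed = 1) |>
    suppressWarnings()
  syn <- out[vapply(out, `[[`, "", "origin") == "smote"]
  vals <- vapply(syn, function(s) s$features[1, 1], 0)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("extracted candidate matrices have the contracted shape", {
  withr::with_seed(17, {
    coh <- generate_cohort(cohort_spec(n_mild = 1, n_moderate = 1,
                                       n_trials = 2, trial_seconds = 4,
                                       seed = 3))
  })
  seg <- segment(bandpass(coh[[1]], "gamma"), 4)[[1]]
  s <- extract_features(seg)
  expect_equal(dim(s$features), c(29, 15))
  expect_identical(colnames(s$features), eegtopo:::CANDIDATE_FEATURES)
  # higher-order columns are constant across nodes (broadcast rule)
  for (nm in eegtopo:::HIGHER_ORDER_NAMES)
    expect_equal(var(s$features[, nm]), 0)
  # paper policy subsetting gives 29 x 11
  sel <- select_features(policy = "paper_fixed")
  expect_equal(dim(s$features[, sel]), c(29, 11))
})
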