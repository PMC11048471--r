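test_that("sample_probe places probes at the prescribed score distribution", {
  set.seed(5)
  ref <- faceverify:::unit_normalize(rnorm(64))

  # zero-variance boundary: mu = 1 collapses onto the reference
  p <- sample_probe(ref, mu = 1, sigma = 0)
  expect_equal(authentication_score(cosine_similarity(ref, p)), 1,
               tolerance = 1e-9)

  # mean recovery at the standard condition's parameters
  as_draws <- replicate(100, {
    pr <- sample_probe(ref, 0.785, 0.004)
    authentication_score(cosine_similarity(ref, pr))
  })
  expect_lt(abs(mean(as_draws) - 0.785), 3 * 0.004 / sqrt(100))

  # SD recovery at the widest masked condition (truncation negligible)
  as_draws <- replicate(10000, {
    pr <- sample_probe(ref, 0.636, 0.027)
    authentication_score(cosine_similarity(ref, pr))
  })
  expect_lt(abs(sd(as_draws) - 0.027), 0.1 * 0.027)

  # every probe is unit norm and the AS equals the drawn cosine's image
  expect_equal(sqrt(sum(sample_probe(ref, 0.7, 0.02)^2)), 1,
               tolerance = 1e-9)
})

test_that("sample_probe rejects invalid parameters", {
  ref <- c(1, 0)
  expect_error(sample_probe(ref, 0.7, -0.1), "sigma")
  expect_error(sample_probe(ref, 1.2, 0.01), "mu")
  expect_error(sample_probe(ref, -0.2, 0.01), "mu")
  expect_error(sample_probe(1, 0.7, 0.01), "dimension")
})

test_that("identity geometry matches the isotropic closed forms", {
  # rho = 0: mean impostor AS -> 0.5, SD -> 0.5/sqrt(dim), checked
  # against direct pairwise sampling within 3 Monte-Carlo SEs
  dim <- 128
  cfg <- sim_config(n_patients = 2000, dim = dim, rho = 0, seed = 31)
  ids <- sample_identity(cfg, n = 2000)
  expect_equal(max(abs(sqrt(rowSums(ids^2)) - 1)), 0, tolerance = 1e-9)
  a <- ids[seq(1, 2000, by = 2), ]
  b <- ids[seq(2, 2000, by = 2), ]
  as_pairs <- 0.5 * rowSums(a * b) + 0.5
  sd_theory <- 0.5 / sqrt(dim)
  n <- length(as_pairs)
  expect_lt(abs(mean(as_pairs) - 0.5), 3 * sd_theory / sqrt(n))
  # SD of a sample SD ~ sd/sqrt(2(n-1))
  expect_lt(abs(sd(as_pairs) - sd_theory), 3 * sd_theory / sqrt(2 * (n - 1)))
})

test_that("population coherence lifts the mean impostor score to 0.5 + rho/2", {
  cfg <- sim_config(n_patients = 2000, dim = 512, rho = 0.01, seed = 77)
  ids <- sample_identity(cfg, n = 2000)
  a <- ids[seq(1, 2000, by = 2), ]
  b <- ids[seq(2, 2000, by = 2), ]
  as_pairs <- 0.5 * rowSums(a * b) + 0.5
  se <- sd(as_pairs) / sqrt(length(as_pairs))
  expect_lt(abs(mean(as_pairs) - 0.505), 3 * se)
})

test_that("build_gallery is reproducible and stable under cohort growth", {
  g1 <- tiny_gallery(n = 3, dim = 16, seed = 11)
  g2 <- tiny_gallery(n = 3, dim = 16, seed = 11)
  expect_identical(g1$embeddings, g2$embeddings)
  expect_identical(g1$index, g2$index)

  g3 <- tiny_gallery(n = 5, dim = 16, seed = 11)
  # per-patient substreams: the first 3 patients are untouched by growth
  expect_identical(g3$embeddings[1:nrow(g1$embeddings), ], g1$embeddings)

  g4 <- tiny_gallery(n = 3, dim = 16, seed = 12)
  expect_false(identical(g1$embeddings, g4$embeddings))
})

test_that("galleries have the right structure down to the degenerate case", {
  g <- tiny_gallery(n = 4, dim = 16)
  expect_equal(nrow(g$embeddings), 4 * 19)
  expect_equal(sum(g$index$role == "reference"), 4)
  expect_equal(max(abs(sqrt(rowSums(g$embeddings^2)) - 1)), 0,
               tolerance = 1e-9)

  g2 <- build_gallery(sim_config(n_patients = 2, dim = 2, seed = 3))
  expect_equal(nrow(g2$embeddings), 38)
  expect_equal(max(abs(sqrt(rowSums(g2$embeddings^2)) - 1)), 0,
               tolerance = 1e-9)
})

test_that("build_gallery names any missing profile condition", {
  prof <- default_profile()
  prof <- prof[prof$condition != "yes.closed.supine.low", ]
  class(prof) <- c("fr_profile", "data.frame")
  cfg <- sim_config(n_patients = 2, dim = 8, seed = 1, profile = prof)
  expect_error(build_gallery(cfg), "yes.closed.supine.low")
})

test_that("genuine score moments track the profile for every condition", {
  g <- build_gallery(sim_config(n_patients = 100, dim = 64, seed = 101))
  sc <- score_all_pairs(g)
  prof <- default_profile()
  gen <- sc[sc$genuine, ]
  for (key in fr_design()$condition) {
    mu <- prof$mean[prof$condition == key]
    sig <- prof$sd[prof$condition == key]
    m <- mean(gen$as[gen$condition == key])
    expect_lt(abs(m - mu), 4 * sig / sqrt(100))
  }
})

test_that("sim_config validates its arguments", {
  expect_error(sim_config(dim = 1), "dim")
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(rho = -0.1), "rho")
})

test_that("gallery CSV round-trips embeddings and labels", {
  g <- tiny_gallery(n = 2, dim = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gallery(g, path)
  g2 <- read_gallery(path)
  expect_equal(g2$embeddings, g$embeddings, tolerance = 1e-12)
  expect_equal(g2$index$condition, g$index$condition)
  expect_equal(g2$config$n_patients, 2)
})
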