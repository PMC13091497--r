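test_that("claw strength is the mean of the per-claw maxima", {
  expect_equal(claw_strength_summary(c(5, 7, 6), c(8, 4, 4)), 7.5)
  expect_equal(claw_strength_summary(3, 5), 4)
  expect_equal(claw_strength_summary(c(9, 9, 9), c(9, 9, 9)), 9)
  expect_error(claw_strength_summary(numeric(0), 5), "at least one")
})

test_that("composite scores follow the sex-specific component rule", {
  expect_equal(composite_trait_score("male", claw_size = 1,
                                     claw_strength = -0.5), 0.5)
  expect_equal(composite_trait_score("female", body_length = 0.2,
                                     claw_strength = 0.3), 0.5)
  expect_error(composite_trait_score("juvenile", claw_size = 1,
                                     claw_strength = 1), "male")
  expect_error(composite_trait_score("male", claw_strength = 1), "claw_size")
})

test_that("perfectly collinear claw dimensions put all variance on PC1", {
  set.seed(3)
  f <- rnorm(20)
  x <- outer(f, c(1, 2, 0.5, 3, 1, 1, 2))
  colnames(x) <- claw_dimension_names()
  pc <- claw_size_pc1(x)
  expect_equal(pc$var_explained, 100)
  # scores proportional to the standardized common factor, positively oriented
  expect_equal(cor(pc$scores, f), 1)
})

test_that("PC1 scores are invariant to the ordering of individuals", {
  set.seed(8)
  f <- rnorm(25)
  x <- 10 + outer(f, rep(0.8, 7)) + matrix(rnorm(25 * 7, sd = 0.5), 25, 7)
  pc <- claw_size_pc1(x)
  perm <- sample(25)
  pc_perm <- claw_size_pc1(x[perm, ])
  expect_equal(pc_perm$scores, pc$scores[perm], tolerance = 1e-9)
})

test_that("variance explained matches the eigen-oracle of the one-factor model", {
  loading <- 0.9
  unique_sd <- 0.44
  # oracle: eigendecomposition of the implied 7x7 correlation matrix
  v <- loading^2 + unique_sd^2
  rho <- loading^2 / v
  R <- matrix(rho, 7, 7)
  diag(R) <- 1
  expected_pct <- 100 * eigen(R, symmetric = TRUE)$values[1] / 7
  set.seed(12)
  f <- rnorm(200)
  x <- sapply(1:7, function(j) loading * f + unique_sd * rnorm(200))
  colnames(x) <- claw_dimension_names()
  pc <- claw_size_pc1(x)
  expect_lt(abs(pc$var_explained - expected_pct), 4)
})

test_that("degenerate claw tables are rejected", {
  x <- matrix(rnorm(14), 2, 7)
  expect_error(claw_size_pc1(x), "at least 3")
  y <- matrix(rnorm(35), 5, 7)
  y[, 3] <- 2
  colnames(y) <- claw_dimension_names()
  expect_error(claw_size_pc1(y), "constant")
})

test_that("derived traits are standardized within sex and ranked per cohort", {
  fx <- generate_empirical_fixture(seed = 5)
  d <- derive_traits(fx$traits)
  for (sx in c("male", "female")) {
    sub <- d[d$sex == sx, ]
    for (col in c("body_length_std", "claw_size", "claw_strength")) {
      expect_equal(mean(sub[[col]]), 0, tolerance = 1e-9)
      expect_equal(sd(sub[[col]]), 1, tolerance = 1e-9)
    }
    expect_setequal(sub$trait_rank, seq_len(nrow(sub)))
  }
  # males: score = claw size + strength; females: body length + strength
  m <- d[d$sex == "male", ]
  expect_equal(m$trait_score, m$claw_size + m$claw_strength)
  f <- d[d$sex == "female", ]
  expect_equal(f$trait_score, f$body_length_std + f$claw_strength)
  ve <- attr(d, "pc1_var_explained")
  expect_true(all(unlist(ve) > 74))
})

test_that("the fixture matches the staged-experiment shape and is seed-stable", {
  fx <- generate_empirical_fixture(seed = 2)
  expect_equal(sum(fx$traits$sex == "male"), 27)
  expect_equal(sum(fx$traits$sex == "female"), 32)
  male_ids <- fx$traits$id[fx$traits$sex == "male"]
  n_male_rand <- sum(fx$contests$round <= 10 &
                       fx$contests$winner_id %in% male_ids)
  expect_gte(n_male_rand, 100)
  expect_lte(n_male_rand, 140)
  expect_equal(max(fx$contests$round), 11)
  fx2 <- generate_empirical_fixture(seed = 2)
  expect_identical(fx, fx2)
})

test_that("a noise-free fixture preserves the latent orderings", {
  fx <- generate_empirical_fixture(seed = 4, unique_sd = 0, side_sd = 0,
                                   trial_sd = 0)
  d <- derive_traits(fx$traits)
  for (sx in c("male", "female")) {
    sub <- d[d$sex == sx, ]
    latent <- fx$latent[[sx]]
    latent <- latent[match(sub$id, latent$id), ]
    expect_equal(order(-sub$claw_size), order(-latent$claw_size))
    expect_equal(order(-sub$claw_strength), order(-latent$claw_strength))
    # derived scores sum *standardized* components, so compare against
    # the standardized latent composite
    latent_std_score <- if (sx == "male") {
      as.numeric(scale(latent$claw_size)) +
        as.numeric(scale(latent$claw_strength))
    } else {
      as.numeric(scale(latent$body_length)) +
        as.numeric(scale(latent$claw_strength))
    }
    expect_equal(order(-sub$trait_score), order(-latent_std_score))
  }
})

test_that("fixture files survive the CSV round trip bit-exactly", {
  fx <- generate_empirical_fixture(seed = 6)
  tdir <- tempdir()
  tp <- file.path(tdir, "traits.csv")
  cp <- file.path(tdir, "contests.csv")
  write_traits(fx$traits, tp)
  write_contests(fx$contests, cp)
  expect_identical(read_traits(tp), fx$traits)
  expect_identical(read_contests(cp), fx$contests)
})

test_that("capture trajectories end at k and start from the trait-only value", {
  fx <- generate_empirical_fixture(seed = 3)
  d <- derive_traits(fx$traits)
  dm <- d[d$sex == "male", ]
  male_recs <- fx$contests[fx$contests$winner_id %in% dm$id, ]
  traj <- capture_trajectory(male_recs, dm, k = 3)
  expect_equal(traj$round, c(0, 2, 4, 6, 8, 10, 11))
  # final fit defines the truth, so the last value is k by construction
  expect_equal(traj$min_selected[traj$round == 11], 3L)
  expect_true(all(traj$min_selected >= 3))
  # contest information accumulates: the trajectory drifts down with
  # bounded upward fluctuation, and the late rounds beat the early ones
  after_burnin <- traj$min_selected[traj$round >= 2]
  expect_true(all(diff(after_burnin) <= 3))
  expect_lt(mean(utils::tail(after_burnin, 3)), mean(utils::head(after_burnin, 2)))
})

test_that("complete contest information over trait-driven outcomes collapses to k", {
  fx <- generate_empirical_fixture(seed = 9, unique_sd = 0, side_sd = 0,
                                   trial_sd = 0)
  # rebuild contests so outcomes follow the trait score exactly, with a
  # full round robin so the final fit sees every pairwise comparison
  d <- derive_traits(fx$traits)
  dm <- d[d$sex == "male", ]
  dom <- setNames(dm$trait_score, dm$id)
  recs <- round_robin_records(dm$id, dom)
  recs$round <- rep_len(1:11, nrow(recs))
  traj <- capture_trajectory(recs, dm, k = 3)
  # the complete record set recovers the trait order exactly, so the
  # truth coincides with the trait ranking: both endpoints sit at k
  expect_equal(traj$min_selected[traj$round == 0], 3L)
  expect_equal(traj$min_selected[traj$round == 11], 3L)
  expect_true(all(traj$min_selected >= 3))
})

test_that("trajectory input contracts are enforced", {
  fx <- generate_empirical_fixture(seed = 3)
  d <- derive_traits(fx$traits)
  expect_error(capture_trajectory(fx$contests, d, k = 3), "single-sex")
  dm <- d[d$sex == "male", ]
  male_recs <- fx$contests[fx$contests$winner_id %in% dm$id, ]
  expect_error(capture_trajectory(male_recs, dm, k = 100), "cohort size")
  expect_error(capture_trajectory(male_recs[male_recs$round <= 4, ], dm,
                                  k = 3), "cover every fit round")
})
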