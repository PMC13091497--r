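test_that("a cyclic tournament forces equal abilities, ranked by tie-break", {
  rec <- data.frame(winner_id = c("A", "B", "C"),
                    loser_id = c("B", "C", "A"))
  fit <- fit_bradley_terry(rec, ids = c("A", "B", "C"), penalty = 0.1)
  expect_equal(fit$ability, rep(0, 3), tolerance = 1e-6)
  expect_equal(setNames(fit$contest_rank, fit$id), c(A = 1L, B = 2L, C = 3L))
  fit2 <- fit_bradley_terry(rec, ids = c("A", "B", "C"), penalty = 0.1,
                            tie_break = c("C", "B", "A"))
  expect_equal(setNames(fit2$contest_rank, fit2$id), c(A = 3L, B = 2L, C = 1L))
})

test_that("penalized abilities match the scalar oracle for two players", {
  rec <- data.frame(winner_id = "A", loser_id = "B")
  ids <- c("A", "B")
  for (lam in c(0.05, 0.1, 1)) {
    fit <- fit_bradley_terry(rec, ids = ids, penalty = lam)
    oracle <- bt_oracle_2(rec, ids, lam)
    expect_gt(fit$ability[1], 0)
    expect_equal(fit$ability[1], -fit$ability[2])
    expect_equal(fit$ability, oracle, tolerance = 1e-6)
  }
})

test_that("penalized abilities match the grid-search oracle for three players", {
  ids <- c("A", "B", "C")
  transitive <- data.frame(winner_id = c("A", "B", "A"),
                           loser_id = c("B", "C", "C"))
  fit <- fit_bradley_terry(transitive, ids = ids, penalty = 0.1)
  oracle <- bt_oracle_3(transitive, ids, 0.1)
  expect_equal(fit$ability, oracle, tolerance = 2e-3)
  expect_true(fit$ability[1] > fit$ability[2] &&
                fit$ability[2] > fit$ability[3])

  lopsided <- data.frame(winner_id = c("A", "A", "B", "C"),
                         loser_id = c("B", "C", "C", "B"))
  fit2 <- fit_bradley_terry(lopsided, ids = ids, penalty = 0.2)
  oracle2 <- bt_oracle_3(lopsided, ids, 0.2)
  expect_equal(fit2$ability, oracle2, tolerance = 2e-3)
})

test_that("fitted win probabilities are shift-invariant and abilities sum to zero", {
  pop <- generate_population(12, male_params(), seed = 31)
  dom <- setNames(pop$true_dominance, pop$id)
  recs <- simulate_contests(pop$id, dom, 4)
  fit <- fit_bradley_terry(recs, ids = pop$id, penalty = 0.1)
  expect_equal(sum(fit$ability), 0, tolerance = 1e-8)
  a <- setNames(fit$ability, fit$id)
  p_before <- plogis(a[recs$winner_id] - a[recs$loser_id])
  a_shift <- a + 5
  p_after <- plogis(a_shift[recs$winner_id] - a_shift[recs$loser_id])
  expect_equal(unname(p_before), unname(p_after))
})

test_that("an overwhelming penalty shrinks all abilities to zero", {
  rec <- data.frame(winner_id = c("A", "A"), loser_id = c("B", "C"))
  fit <- fit_bradley_terry(rec, ids = c("A", "B", "C"), penalty = 1e6)
  expect_equal(fit$ability, rep(0, 3), tolerance = 1e-4)
})

test_that("separable records at zero penalty are surfaced, not returned", {
  rec <- data.frame(winner_id = c("A", "A", "B"),
                    loser_id = c("B", "C", "C"))
  expect_error(fit_bradley_terry(rec, ids = c("A", "B", "C"), penalty = 0),
               "penalty")
})

test_that("one full round robin recovers the dominance order exactly", {
  for (n in c(5, 8, 12)) {
    set.seed(100 + n)
    ids <- sprintf("P%02d", 1:n)
    dom <- setNames(rnorm(n), ids)
    recs <- round_robin_records(ids, dom)
    fit <- fit_bradley_terry(recs, ids = ids, penalty = 0.05)
    expect_equal(cor(fit$contest_rank, rank_values(dom[fit$id]),
                     method = "spearman"), 1)
  }
})

test_that("repeating round robins never degrades rank recovery", {
  set.seed(55)
  ids <- sprintf("P%02d", 1:8)
  dom <- setNames(rnorm(8), ids)
  true_ranks <- rank_values(dom)
  one <- round_robin_records(ids, dom)
  cors <- sapply(1:3, function(reps) {
    recs <- do.call(rbind, replicate(reps, one, simplify = FALSE))
    fit <- fit_bradley_terry(recs, ids = ids, penalty = 0.1)
    cor(fit$contest_rank, true_ranks[fit$id], method = "spearman")
  })
  expect_true(all(diff(cors) >= 0))
})

test_that("uncontested individuals sit at ability zero, ranked after contested equals", {
  rec <- data.frame(winner_id = c("A", "B", "C"),
                    loser_id = c("B", "C", "A"))
  fit <- fit_bradley_terry(rec, ids = c("A", "B", "C", "D"), penalty = 0.1,
                           tie_break = c("D", "A", "B", "C"))
  d_row <- fit[fit$id == "D", ]
  expect_equal(d_row$ability, 0, tolerance = 1e-6)
  expect_equal(d_row$n_contests, 0L)
  # D ties the cyclic trio at 0 but ranks after them despite tie-break priority
  expect_equal(d_row$contest_rank, 4L)
})

test_that("record validation rejects unknown ids, self-contests and empty sets", {
  ids <- c("A", "B")
  expect_error(fit_bradley_terry(data.frame(winner_id = "A", loser_id = "Z"),
                                 ids), "not present")
  expect_error(fit_bradley_terry(data.frame(winner_id = "A", loser_id = "A"),
                                 ids), "self-contest")
  expect_error(fit_bradley_terry(data.frame(winner_id = character(0),
                                            loser_id = character(0)), ids),
               "empty")
  expect_error(fit_bradley_terry_ml(data.frame(winner_id = "A", loser_id = "Z"),
                                    ids), "not present")
})

test_that("the maximum-likelihood fit agrees with the penalized fit as the penalty vanishes", {
  # non-separable, asymmetric records: finite distinct ML abilities
  ids <- c("A", "B", "C")
  rec <- data.frame(
    winner_id = c("A", "A", "A", "B", "B", "B", "B", "C", "A", "A", "C", "C"),
    loser_id  = c("B", "B", "B", "A", "C", "C", "C", "B", "C", "C", "A", "A")
  )
  ml <- fit_bradley_terry_ml(rec, ids = ids)
  expect_true(attr(ml, "converged"))
  ridge <- fit_bradley_terry(rec, ids = ids, penalty = 1e-8)
  expect_equal(ml$ability, ridge$ability, tolerance = 1e-4)
  expect_equal(ml$contest_rank, ridge$contest_rank)
})

test_that("ml fit on separable records still returns the consistent ranking", {
  pop <- generate_population(20, male_params(), seed = 77)
  dom <- setNames(pop$true_dominance, pop$id)
  recs <- round_robin_records(pop$id, dom)
  ml <- fit_bradley_terry_ml(recs, ids = pop$id)
  expect_false(attr(ml, "converged"))
  expect_equal(cor(ml$contest_rank, rank_values(dom[ml$id]),
                   method = "spearman"), 1)
})

test_that("contest_ranks demands complete abilities and honours tie-breaks", {
  ab <- data.frame(id = c("A", "B"), ability = c(0.5, -0.5),
                   n_contests = c(1L, 1L))
  expect_equal(contest_ranks(ab), c(A = 1L, B = 2L))
  ab_tied <- data.frame(id = c("A", "B"), ability = c(0, 0),
                        n_contests = c(1L, 1L))
  expect_equal(contest_ranks(ab_tied, tie_break = c("B", "A")),
               c(A = 2L, B = 1L))
  ab_na <- data.frame(id = "A", ability = NA_real_, n_contests = 0L)
  expect_error(contest_ranks(ab_na), "ability")
  expect_error(contest_ranks(ab, tie_break = "A"), "every id")
})
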