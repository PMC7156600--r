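test_that("seed expansion recovers the planted cluster and respects step counts", {
  sim <- small_sim()
  calls <- booleanize(sim$expr)
  uni <- sim$truth$probe_id[sim$truth$label == "universal"]

  tr <- suppressMessages(expand_seed(calls, "UNI001_at"))
  expect_setequal(tr$sets$A, setdiff(uni, "UNI001_at"))
  expect_identical(tr$sets$B, tr$sets$A) # nothing new joins later rounds
  expect_identical(tr$sets$C, tr$sets$A)
  expect_setequal(tr$candidates, uni)
  expect_false("UNI001_at" %in% tr$sets$A)

  tr1 <- suppressMessages(expand_seed(calls, "UNI001_at", steps = 1))
  expect_setequal(tr1$candidates, union(tr1$sets$A, "UNI001_at"))

  expect_error(suppressMessages(
    expand_seed(calls, "MISSING_at")), "not present")
})

test_that("a seed without equivalents warns and yields an empty expansion", {
  sim <- small_sim()
  calls <- booleanize(sim$expr)
  expect_warning(
    tr <- suppressMessages(expand_seed(calls, "NSE0001_at")),
    "no Boolean-equivalent"
  )
  expect_length(tr$sets$A, 0)
  expect_identical(tr$candidates, "NSE0001_at")

  const <- rbind(sim$expr, CST001_at = rep(5, ncol(sim$expr)))
  expect_error(suppressMessages(
    expand_seed(booleanize(const), "CST001_at")), "degenerate")
})

test_that("pair scores follow the r^2 + s^2 definition with slope symmetrization", {
  a <- c(1.2, 2.5, 3.1, 4.8, 5.3, 6.9)
  ps <- pair_score(a, a)
  expect_equal(ps$r, 1)
  expect_equal(ps$s, 1)
  expect_equal(ps$score, 2)

  ps2 <- pair_score(a, 2 * a)
  expect_equal(ps2$r, 1)
  expect_equal(ps2$s, 0.5)
  expect_equal(ps2$score, 1.25)
  # direction-free for exact linear relations
  expect_identical(pair_score(2 * a, a)$score, ps2$score)

  # r and slope agree with lm()/cor() before flooring and inversion
  set.seed(2)
  x <- rnorm(40, 5)
  y <- 0.6 * x + rnorm(40, 0, 0.3)
  ps3 <- pair_score(x, y)
  expect_equal(ps3$r, cor(x, y))
  s_xy <- unname(coef(lm(y ~ x))[2])
  s_yx <- unname(coef(lm(x ~ y))[2])
  expect_equal(ps3$s, min(min(s_xy, 1 / s_xy), min(s_yx, 1 / s_yx)))

  # independent pairs score near zero; anti-correlated pairs floor at zero
  set.seed(3)
  big <- rnorm(2000)
  expect_lt(pair_score(big, rnorm(2000))$score, 0.01)
  expect_equal(pair_score(a, -a)$score, 0)

  expect_error(pair_score(a, rep(1, 6)), "constant")
  expect_error(pair_score(1:2, 2:1), "3 paired")
})

test_that("the score matrix is symmetric with a self-score diagonal", {
  sim <- small_sim()
  L <- c("UNI001_at", "UNI002_at", "UNI003_at", "SUB001_at", "NSE0001_at")
  M <- score_matrix(sim$expr, L)
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(2, 5))
  # off-diagonal entries match the per-pair route
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M[i, j],
                 pair_score(sim$expr[L[i], ], sim$expr[L[j], ])$score,
                 tolerance = 1e-12)
  }
  two <- score_matrix(rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4)), c("A", "B"))
  expect_equal(unname(two), matrix(2, 2, 2))
  expect_error(score_matrix(sim$expr, "NOPE"), "absent")
})

test_that("gene scores follow the rank-weighted definition and its bounds", {
  M <- matrix(2, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(gene_scores(M)), c(0.5, 0.5)) # the (len-1)/2 bound

  # all-zero off-diagonal rows: only the diagonal 2 carries rank weight
  for (len in c(3, 5, 8)) {
    D <- diag(2, len)
    dimnames(D) <- list(paste0("p", 1:len), paste0("p", 1:len))
    expect_equal(unname(gene_scores(D)), rep((len - 1) / len, len))
  }

  set.seed(21)
  R <- matrix(runif(100, 0, 2), 10)
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  diag(R) <- 2
  dimnames(R) <- list(paste0("p", 1:10), paste0("p", 1:10))
  gs <- gene_scores(R)
  expect_equal(unname(gs), oracle_gene_scores(R))
  expect_true(all(gs >= 0 & gs <= (10 - 1) / 2))
})

test_that("the step threshold on gene scores selects the high mode", {
  gs <- c(p1 = 0.1, p2 = 0.1, p3 = 0.9, p4 = 0.9)
  sel <- select_by_threshold(gs)
  expect_equal(sel$threshold, 0.5)
  expect_setequal(sel$selected, c("p3", "p4"))

  expect_warning(all_sel <- select_by_threshold(c(a = 1, b = 1, c = 1)),
                 "constant")
  expect_setequal(all_sel$selected, c("a", "b", "c"))
  expect_true(all_sel$degenerate)
  expect_error(select_by_threshold(c(a = 1)), "at least 2")
})

test_that("the empirical null is deterministic and scales by the printed formulas", {
  sim <- small_sim()
  n1 <- empirical_null(sim$expr, len_l = 12, n_pairs = 2000, rng_seed = 9,
                       threshold = 4)
  n2 <- empirical_null(sim$expr, len_l = 12, n_pairs = 2000, rng_seed = 9,
                       threshold = 4)
  expect_identical(n1$scores, n2$scores)
  expect_identical(n1$z, n2$z)

  expect_equal(n1$e_gs, n1$mean_score * 11 / 4)
  expect_equal(n1$sd_gs, sqrt(n1$var_score) * 11 / 4)
  expect_equal(n1$z, (4 - n1$e_gs) / n1$sd_gs)
  expect_equal(n1$p_value, pnorm(n1$z, lower.tail = FALSE))

  # a noise-only compendium scores near zero, so any real threshold is extreme
  set.seed(10)
  noise <- matrix(rnorm(120 * 80), 120,
                  dimnames = list(sprintf("N%03d", 1:120), sprintf("S%02d", 1:80)))
  nn <- empirical_null(noise, len_l = 10, n_pairs = 1000, rng_seed = 1,
                       threshold = 1)
  expect_lt(nn$mean_score, 0.1)
  expect_gt(nn$z, 5)
  expect_lt(nn$p_value, 1e-6)

  # requesting more pairs than exist uses every distinct pair once
  tiny <- noise[1:50, ]
  all_pairs <- empirical_null(tiny, len_l = 5, n_pairs = 1e6)
  expect_identical(all_pairs$n_pairs + all_pairs$n_dropped, 1225L)

  expect_error(empirical_null(noise[1, , drop = FALSE], 5), "at least 2 probes")
  expect_error(empirical_null(noise, 5, n_pairs = 10), "at least 1000")
})

test_that("run_becc composes the pipeline deterministically", {
  sim <- small_sim()
  cfg <- becc_config("UNI002_at", null_pairs = 2000, rng_seed = 31)
  res1 <- suppressMessages(run_becc(sim$expr, cfg, sim$annotation))
  res2 <- suppressMessages(run_becc(sim$expr, cfg, sim$annotation))
  expect_identical(tidy(res1), tidy(res2))
  expect_identical(glance(res1), glance(res2))

  uni_genes <- unique(sim$truth$gene_symbol[sim$truth$label == "universal"])
  expect_setequal(selected_genes(res1), uni_genes)
  expect_false(any(grepl("SGENE|NGENE", selected_genes(res1))))
  expect_lt(glance(res1)$p_value, 0.01)

  # raising the sparsity threshold can only shrink the candidate list
  cfg_strict <- becc_config("UNI002_at", s_threshold = 8, null_pairs = 2000,
                            rng_seed = 31)
  res_strict <- suppressWarnings(suppressMessages(
    run_becc(sim$expr, cfg_strict, sim$annotation)))
  expect_true(all(res_strict$trace$candidates %in% res1$trace$candidates))
  sel_strict <- tidy(res_strict)$probe_id[tidy(res_strict)$selected]
  expect_true(all(sel_strict %in% res1$trace$candidates))
})

test_that("tidy, glance and autoplot expose the result surface", {
  sim <- small_sim()
  cfg <- becc_config("UNI001_at", null_pairs = 1000, rng_seed = 2)
  res <- suppressMessages(run_becc(sim$expr, cfg, sim$annotation))
  td <- tidy(res)
  expect_named(td, c("probe_id", "gene_symbols", "gs", "rank", "selected",
                     "dynamic_range"))
  expect_identical(td$rank, seq_len(nrow(td)))
  expect_false(is.unsorted(rev(td$gs)))
  expect_true(all(td$dynamic_range > 0))
  gl <- glance(res)
  expect_identical(gl$len_l, length(res$trace$candidates))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
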