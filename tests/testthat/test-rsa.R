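# Neural RDMs, the RSA association statistic, contrasts and trajectories.

test_that("correlation-distance RDM hits its defining values", {
  base <- rnorm(20)
  pats <- rbind(a = base, b = 2 * base + 1,            # perfectly correlated
                c = -base,                             # sign-flipped
                d = rnorm(20))
  nr <- neural_rdm(pats)
  m <- nr$matrix
  expect_equal(m["a", "b"], 0, tolerance = 1e-12)
  expect_equal(m["a", "c"], 2, tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 2))
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  # exactly orthogonalized patterns -> dissimilarity 1
  x <- rnorm(20)
  y <- rnorm(20)
  y <- y - mean(y)
  xc <- x - mean(x)
  y <- y - sum(y * xc) / sum(xc^2) * xc
  expect_equal(neural_rdm(rbind(x, y))$matrix[1, 2], 1, tolerance = 1e-10)
  # zero-variance pattern becomes missing
  expect_warning(nr0 <- neural_rdm(rbind(a = rep(1, 20), b = rnorm(20))),
                 "zero-variance")
  expect_true(is.na(nr0$matrix["a", "b"]))
  expect_error(neural_rdm(matrix(1, 1, 5)), "at least 2")
})

test_that("the RSA effect is a rank statistic with the stated conventions", {
  set.seed(21)
  n <- 12
  M <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
  ids <- sprintf("t%02d", 1:n)
  dimnames(M) <- list(ids, ids)
  # monotone transform of the model -> association exactly 1
  N <- exp(M)
  diag(N) <- 0
  expect_equal(rsa_effect(M, N), 1, tolerance = 1e-12)
  # invariance to monotone transform of either matrix
  E <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
  dimnames(E) <- list(ids, ids)
  expect_equal(rsa_effect(M, E), rsa_effect(sqrt(M), E), tolerance = 1e-12)
  # permutation null centred at zero
  vals <- replicate(200, {
    p <- sample(n)
    Np <- E[p, p]
    dimnames(Np) <- list(ids, ids)
    rsa_effect(M, Np)
  })
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(rsa_effect(M[1:2, 1:2], E[1:2, 1:2]), "fewer than 3")
  expect_error(rsa_effect(M, E[1:5, 1:5]), "do not match")
})

test_that("a two-valued model RDM reduces to a mean-rank contrast", {
  # oracle: point-biserial correlation between the binary model entries
  # and the ranks of the neural entries, written out from sums
  set.seed(22)
  n <- 10
  grp <- rep(c("A", "B"), each = n / 2)
  M <- outer(grp, grp, function(a, b) ifelse(a == b, 0, 1))
  ids <- sprintf("t%02d", 1:n)
  dimnames(M) <- list(ids, ids)
  N <- as.matrix(dist(matrix(rnorm(n * 4), n, 4)))
  dimnames(N) <- list(ids, ids)
  x <- M[lower.tri(M)]
  ry <- rank(N[lower.tri(N)])
  rx <- rank(x)
  m_pairs <- length(x)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  # and the sign agrees with the within-vs-between mean-rank difference
  mr_diff <- mean(ry[x == 1]) - mean(ry[x == 0])
  expect_equal(rsa_effect(M, N), oracle, tolerance = 1e-12)
  expect_equal(sign(rsa_effect(M, N)), sign(mr_diff))
})

test_that("repeat-minus-novel contrast is an antisymmetric cell difference", {
  eff <- data.frame(
    subject = "s01", roi = "aud", phase = rep(c("encoding", "delay"), each = 2),
    seq_type = rep(c("repeat", "novel"), 2), run = "pooled",
    value = c(0.5, 0.2, 0.3, 0.3)
  )
  ctr <- repeat_novel_contrast(eff)
  expect_equal(ctr$contrast[ctr$phase == "encoding"], 0.3)
  expect_equal(ctr$contrast[ctr$phase == "delay"], 0)
  swapped <- eff
  swapped$seq_type <- ifelse(eff$seq_type == "repeat", "novel", "repeat")
  expect_equal(repeat_novel_contrast(swapped)$contrast, -ctr$contrast)
  expect_warning(repeat_novel_contrast(eff[-1, ]), "unmatched")
})

test_that("pooled association is not the mean of per-run associations", {
  # constructed counterexample: within each run model and neural agree,
  # but the run-level offsets reverse the pooled ranking
  ids <- sprintf("t%02d", 1:8)
  M <- matrix(0, 8, 8, dimnames = list(ids, ids))
  N <- matrix(0, 8, 8, dimnames = list(ids, ids))
  r1 <- 1:4; r2 <- 5:8
  set.seed(23)
  M[r1, r1] <- as.matrix(dist(1:4))
  M[r2, r2] <- as.matrix(dist(1:4))
  N[r1, r1] <- as.matrix(dist(1:4))
  N[r2, r2] <- 2 - 0.1 * as.matrix(dist(1:4))
  diag(N) <- 0
  # cross-run blocks: model large, neural small
  M[r1, r2] <- 10; M[r2, r1] <- 10
  N[r1, r2] <- 0.01; N[r2, r1] <- 0.01
  per_run <- c(rsa_effect(M[r1, r1], N[r1, r1]),
               rsa_effect(M[r2, r2], N[r2, r2]))
  pooled <- rsa_effect(M, N)
  expect_false(isTRUE(all.equal(pooled, mean(per_run), tolerance = 1e-3)))
})

test_that("per-run slopes recover a linear trend", {
  eff <- expand.grid(subject = "s01", roi = "aud", phase = "encoding",
                     seq_type = c("repeat", "novel"), run = as.character(1:8),
                     stringsAsFactors = FALSE)
  eff$value <- ifelse(eff$seq_type == "repeat",
                      0.05 * as.numeric(eff$run), 0.1)
  sl <- per_run_slopes(eff)
  expect_equal(sl$slope[sl$seq_type == "repeat"], 0.05, tolerance = 1e-12)
  expect_equal(sl$slope[sl$seq_type == "novel"], 0, tolerance = 1e-12)
})

test_that("subject-level pipeline returns a complete long table", {
  d <- tiny_design(seed = 8)
  sim <- simulate_subject(d, tiny_params(seed = 12))
  eff <- subject_rsa_effects(sim, d, phases = c("encoding", "delay"),
                             subject = "s07")
  expect_setequal(unique(eff$run), c("pooled", "1", "2"))
  expect_setequal(unique(eff$seq_type), c("repeat", "novel"))
  expect_setequal(unique(eff$phase), c("encoding", "delay"))
  expect_equal(nrow(eff), 1 * 2 * 2 * 3)  # roi x phase x type x run-stratum
  expect_true(all(is.finite(eff$value[eff$run == "pooled"])))
  expect_true(all(abs(eff$value) <= 1, na.rm = TRUE))
})
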