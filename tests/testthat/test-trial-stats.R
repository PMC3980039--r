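# Brute-force normal-equations ANCOVA oracle: explicit design matrix,
# beta = (X'X)^-1 X'y, vcov = s^2 (X'X)^-1.
ancova_oracle <- function(base, endp, h, arm, comparator) {
  arm <- relevel(factor(arm), ref = comparator)
  X <- cbind(1, base, as.numeric(h),
             sapply(levels(arm)[-1], function(a) as.numeric(arm == a)))
  beta <- solve(t(X) %*% X, t(X) %*% endp)
  res <- endp - X %*% beta
  df <- length(endp) - ncol(X)
  s2 <- sum(res^2) / df
  V <- s2 * solve(t(X) %*% X)
  idx <- 3 + seq_len(nlevels(arm) - 1)
  list(diff = as.numeric(beta[idx]), se = unname(sqrt(diag(V)[idx])),
       df = df, beta = as.numeric(beta))
}

test_that("with inert covariates the LSM difference equals the raw
           mean-change difference", {
  rec <- change_records(
    subject_id = sprintf("s%d", 1:6),
    arm = rep(c("A", "B"), each = 3),
    baseline_value = rep(5, 6),
    endpoint_value = c(5 + c(1, 2, 3), 5 + c(3, 4, 5)),
    baseline_hba1c_high = FALSE)
  res <- ancova_lsm_change(rec, comparator_arm = "B")
  expect_equal(res$contrasts$lsm_diff, -2)
  expect_equal(res$per_arm$lsm_change[res$per_arm$arm == "A"], 2)
  expect_equal(res$per_arm$lsm_change[res$per_arm$arm == "B"], 4)
})

test_that("ANCOVA matches the brute-force normal-equations oracle", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:10, 3, replace = TRUE)
    arm <- rep(c("ctrl", "t1", "t2"), times = n)
    base <- rnorm(sum(n), 10, 2)
    h <- runif(sum(n)) < 0.4
    if (all(h) || !any(h)) h[1] <- !h[1]
    endp <- 2 + 0.8 * base + 0.5 * h + 1.5 * (arm == "t1") -
      0.7 * (arm == "t2") + rnorm(sum(n))
    rec <- change_records(sprintf("s%d", seq_along(arm)), arm, base, endp, h)
    res <- ancova_lsm_change(rec, "ctrl")
    o <- ancova_oracle(base, endp, h, arm, "ctrl")
    expect_equal(res$contrasts$lsm_diff, o$diff, tolerance = 1e-8)
    expect_equal(res$contrasts$sem, o$se, tolerance = 1e-8)
    expect_equal(res$df, o$df)
    p_o <- 2 * pt(-abs(o$diff / o$se), o$df)
    expect_equal(res$contrasts$p_value, p_o, tolerance = 1e-8)
    # LSM at grand-mean covariates from the oracle coefficients
    lsm_o <- o$beta[1] + o$beta[2] * mean(base) + o$beta[3] * mean(h) +
      c(0, o$diff)
    expect_equal(res$per_arm$lsm_endpoint, lsm_o, tolerance = 1e-8)
  }
})

test_that("LSM differences are invariant to shifting all endpoints and
           log-scale testing leaves raw-scale estimates unchanged", {
  set.seed(77)
  arm <- rep(c("ctrl", "trt"), each = 8)
  base <- rlnorm(16, 3, 0.3)
  endp <- base * exp(0.2 * (arm == "trt")) * rlnorm(16, 0, 0.1)
  h <- rep(c(TRUE, FALSE), 8)
  rec <- change_records(sprintf("s%d", 1:16), arm, base, endp, h)
  res <- ancova_lsm_change(rec, "ctrl")
  rec2 <- rec; rec2$endpoint_value <- rec$endpoint_value + 100
  res2 <- ancova_lsm_change(rec2, "ctrl")
  expect_equal(res2$contrasts$lsm_diff, res$contrasts$lsm_diff)
  res_log <- ancova_lsm_change(rec, "ctrl", log_scale = TRUE)
  expect_equal(res_log$contrasts$lsm_diff, res$contrasts$lsm_diff)
  expect_false(isTRUE(all.equal(res_log$contrasts$p_value,
                                res$contrasts$p_value)))
  o_log <- ancova_oracle(log(base), log(endp), h, arm, "ctrl")
  expect_equal(res_log$contrasts$p_value,
               2 * pt(-abs(o_log$diff / o_log$se), o_log$df),
               tolerance = 1e-8)
})

test_that("degenerate ANCOVA designs are rejected with a reason", {
  rec <- change_records(sprintf("s%d", 1:6), rep("A", 6), rnorm(6),
                        rnorm(6), FALSE)
  expect_error(ancova_lsm_change(rec, "A"), "2 arms")
  rec2 <- change_records(sprintf("s%d", 1:5),
                         c("A", "A", "A", "B", "B"),
                         rnorm(5), rnorm(5), FALSE)
  expect_error(ancova_lsm_change(rec2, "A"), "fewer than 3")
  expect_error(ancova_lsm_change(rec2, "C"), "no records")
})

test_that("Kruskal-Wallis on changes: identical groups, enumeration
           oracle, and monotone-transform invariance", {
  rec <- change_records(sprintf("s%d", 1:6), rep(c("A", "B"), each = 3),
                        rep(0, 6), c(1, 2, 3, 1, 2, 3), FALSE)
  kw <- kruskal_wallis_change(rec)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)

  # exhaustive enumeration on the 6-observation instance (1,2,3) vs
  # (10,11,12): the H statistic of every label assignment
  x <- c(1, 2, 3, 10, 11, 12)
  H_of <- function(members) {
    r <- rank(x)
    R1 <- sum(r[members]); R2 <- sum(r[-members])
    12 / (6 * 7) * (R1^2 / 3 + R2^2 / 3) - 3 * 7
  }
  rec2 <- change_records(sprintf("s%d", 1:6), rep(c("A", "B"), each = 3),
                         rep(0, 6), x, FALSE)
  kw2 <- kruskal_wallis_change(rec2)
  expect_equal(kw2$statistic, H_of(1:3), tolerance = 1e-12)
  combs <- combn(6, 3)
  H_null <- apply(combs, 2, H_of)
  expect_equal(max(H_null), kw2$statistic)   # observed split is extremal
  expect_equal(kw2$p_value, pchisq(kw2$statistic, 1, lower.tail = FALSE))

  # invariance under strictly monotone transforms of the pooled changes
  set.seed(9)
  y <- rnorm(12)
  rec3 <- change_records(sprintf("s%d", 1:12), rep(c("A", "B", "C"), 4),
                         rep(0, 12), y, FALSE)
  rec4 <- rec3; rec4$endpoint_value <- exp(y)
  expect_equal(kruskal_wallis_change(rec3)$statistic,
               kruskal_wallis_change(rec4)$statistic)
})
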