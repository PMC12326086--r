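test_that("response transforms are the identity and the square root", {
  expect_equal(apply_transform(25, "sqrt"), 5)
  expect_equal(apply_transform(c(1, 4, 9), "sqrt"), c(1, 2, 3))
  x <- rnorm(10)
  expect_identical(apply_transform(x, "identity"), x)
  expect_error(apply_transform(-1, "sqrt"), "non-negative")
})

test_that("VIF pruning removes collinear predictors and keeps clean ones", {
  set.seed(31)
  n <- 400
  # near-collinear pair: correlation 0.95 -> VIF = 1/(1-0.95^2) ~ 10.26
  x1 <- rnorm(n)
  x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(n)
  x3 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  pr <- vif_prune(d, c("x1", "x2", "x3"), threshold = 5)
  expect_equal(nrow(pr$removed), 1)
  expect_true(pr$removed$term %in% c("x1", "x2"))
  expect_gt(pr$removed$vif, 5)
  expect_equal(pr$removed$vif, 1 / (1 - cor(x1, x2)^2), tolerance = 0.5)

  # exact collinearity: the later-ordered offender goes, flagged infinite
  d2 <- data.frame(a = x1, b = 2 * x1, c = x3)
  pr2 <- vif_prune(d2, c("a", "b", "c"))
  expect_equal(pr2$removed$term, "b")
  expect_equal(pr2$removed$vif, Inf)
  expect_setequal(pr2$retained, c("a", "c"))

  # orthogonal predictors all retained
  pr3 <- vif_prune(data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n)),
                   c("u", "v", "w"))
  expect_equal(nrow(pr3$removed), 0)
  expect_length(pr3$retained, 3)

  # interactions follow their parents
  pr4 <- vif_prune(d2, c("a", "b", "c", "a:c", "b:c"))
  expect_setequal(pr4$retained, c("a", "c", "a:c"))
})

test_that("subset enumeration respects marginality", {
  expect_length(enumerate_subsets(c("A", "B", "C")), 8)
  s <- enumerate_subsets(c("A", "B", "A:B"))
  expect_length(s, 5)
  expect_true(any(vapply(s, function(x) length(x) == 0, logical(1))))
  expect_false(any(vapply(s, function(x)
    "A:B" %in% x && !all(c("A", "B") %in% x), logical(1))))
  expect_length(enumerate_subsets("A"), 2)
  expect_error(enumerate_subsets(paste0("t", 1:20)), "refusing")
})

test_that("enumerated counts match the closed form on random term lattices", {
  set.seed(32)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    mains <- paste0("m", seq_len(k))
    pairs <- utils::combn(mains, 2)
    take <- sample(ncol(pairs), sample(0:min(3, ncol(pairs)), 1))
    inters <- apply(pairs[, take, drop = FALSE], 2, paste, collapse = ":")
    terms <- c(mains, inters)
    # closed form: sum over main subsets of 2^(eligible interactions)
    count <- 0
    for (mask in 0:(2^k - 1)) {
      present <- mains[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
      elig <- sum(vapply(inters, function(tt)
        all(strsplit(tt, ":")[[1]] %in% present), logical(1)))
      count <- count + 2^elig
    }
    expect_length(enumerate_subsets(terms), count)
  }
})

test_that("mixed-model fits recover structure and flag boundary variance", {
  set.seed(33)
  d <- make_lmm_data(n_per = 40)
  fit <- fit_lmm(d, "y", c("habitat", "flight_time"))
  expect_s3_class(fit, "lmm_fit")
  expect_false(fit$singular)
  expect_true(fit$converged)
  expect_true(is.finite(fit$aic))
  expect_gt(fit$r2, 0); expect_lt(fit$r2, 1)

  # zero bird/loft variance -> boundary -> singular
  d0 <- make_lmm_data(n_per = 40, bird_sd = 0, loft_sd = 0)
  expect_true(fit_lmm(d0, "y", "habitat")$singular)

  # noiseless linear response: slope recovered exactly
  dn <- make_lmm_data(n_per = 40, effects = c(wooded = 0, urban = 0),
                      resid_sd = 0.5)
  dn$y <- 2 + 3 * dn$flight_time + as.numeric(factor(dn$bird_id))
  fit3 <- fit_lmm(dn, "y", "flight_time")
  expect_equal(unname(lme4::fixef(fit3$fit)["flight_time"]), 3,
               tolerance = 1e-6)

  # intercept-only model explains no variance by fixed effects
  di <- make_lmm_data(n_per = 30)
  expect_equal(fit_lmm(di, "y", character(0))$r2, 0, tolerance = 1e-9)
})

test_that("the Delta-AIC / r2 / parsimony rule picks the documented winner", {
  A <- fake_fit(100, 0.30, 2)
  B <- fake_fit(101.5, 0.32, 3)
  C <- fake_fit(103, 0.40, 4)
  expect_identical(select_best(list(A, B, C)), B)
  expect_identical(select_best(list(C, A, B)), B)   # order invariance

  A2 <- fake_fit(100, 0.30000, 2)
  B2 <- fake_fit(101.9, 0.30000, 4)
  expect_identical(select_best(list(A2, B2)), A2)   # r2 tie -> fewest terms
  expect_identical(select_best(list(B2, A2)), A2)

  single <- fake_fit(50, 0.1, 1)
  expect_identical(select_best(list(single)), single)
  expect_error(select_best(list(fake_fit(1, 0.5, 1, singular = TRUE))),
               "non-singular")
})

test_that("closed-form Cook's distances match leave-one-out refits", {
  set.seed(34)
  n <- 200
  d <- data.frame(bird_id = "b", loft_id = "l",
                  flight_time = rnorm(n), iteration = rnorm(n))
  d$y <- 1 + 2 * d$flight_time - d$iteration + rnorm(n)
  got <- cooks_distances(d, "y", c("flight_time", "iteration"))
  X <- cbind(1, d$flight_time, d$iteration)
  fit <- lm.fit(X, d$y)
  p <- 3
  s2 <- sum(fit$residuals^2) / (n - p)
  brute <- vapply(seq_len(n), function(i) {
    fi <- lm.fit(X[-i, , drop = FALSE], d$y[-i])
    pred_all <- X %*% fi$coefficients
    sum((X %*% fit$coefficients - pred_all)^2) / (p * s2)
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a gross outlier is removed by the 4/n rule and the model refit", {
  set.seed(35)
  d <- make_lmm_data(n_per = 3, effects = c(wooded = 0, urban = 0),
                     resid_sd = 1)
  d <- d[1:50, ]   # spans all three lofts
  d$y <- d$flight_time * 0.01 + rnorm(50, 0, 1)
  d$y[25] <- d$y[25] + 100        # 100 sigma shift
  dist <- cooks_distances(d, "y", "flight_time")
  expect_equal(which(dist > 4 / 50), 25)

  fit <- fit_lmm(d, "y", "flight_time")
  cr <- cooks_refit(fit, d)
  expect_gte(cr$removed, 1)
  d2 <- d; d2$y[25] <- d2$y[25] - 100
  fit2 <- fit_lmm(d2, "y", "flight_time")
  cr2 <- cooks_refit(fit2, d2, threshold = 1e6)  # nothing exceeds
  expect_equal(cr2$removed, 0)
  expect_equal(cr2$fit$aic, fit2$aic, tolerance = 1e-6)
})

test_that("habitat-vs-identity independence diagnostic discriminates", {
  set.seed(36)
  n <- 600
  birds <- sample(paste0("b", 1:12), n, replace = TRUE)
  ind <- data.frame(bird_id = birds,
                    habitat = sample(c("open", "wooded", "urban"), n,
                                     replace = TRUE))
  r1 <- layer_independence_check(ind)
  expect_gt(r1$p_value, 1e-6)

  det <- data.frame(bird_id = birds,
                    habitat = c("open", "wooded", "urban")[
                      (as.integer(factor(birds)) %% 3) + 1])
  r2 <- layer_independence_check(det)
  expect_lt(r2$p_value, 1e-6)

  one <- data.frame(bird_id = birds, habitat = "open")
  expect_error(layer_independence_check(one), "single level")
})

test_that("independence diagnostic holds its type-I error rate", {
  set.seed(37)
  reps <- 100
  ns <- vapply(seq_len(reps), function(i) {
    d <- data.frame(bird_id = sample(paste0("b", 1:10), 300, replace = TRUE),
                    habitat = sample(c("open", "wooded", "urban"), 300,
                                     replace = TRUE))
    layer_independence_check(d)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ns), 0.94)
})

test_that("habitat fixed effects are recovered within 2 SE across replicates", {
  set.seed(38)
  hits <- replicate(50, {
    d <- make_lmm_data(n_per = 40)
    fit <- fit_lmm(d, "y", c("habitat", "flight_time"))
    sm <- summary(fit$fit)$coefficients
    truth <- attr(d, "effects")
    all(abs(sm[c("habitatwooded", "habitaturban"), "Estimate"] -
              truth[c("wooded", "urban")]) <=
          2 * sm[c("habitatwooded", "habitaturban"), "Std. Error"])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("full selection run reports a coefficient table and outlier count", {
  set.seed(39)
  d <- make_lmm_data(n_per = 40)
  rep_ <- select_model(d, "y", c("habitat", "flight_time", "iteration",
                                 "habitat:flight_time"))
  expect_s3_class(rep_, "model_report")
  expect_identical(rep_$status, "ok")
  expect_true("habitat" %in% rep_$final$terms)
  expect_true(all(c("term", "estimate", "se", "F", "p") %in%
                    names(rep_$table)))
  he <- habitat_effects(rep_$final)
  expect_equal(he$estimate[he$level == "wooded"], -0.7, tolerance = 0.3)
  expect_equal(he$estimate[he$level == "urban"], 0.7, tolerance = 0.3)
})
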