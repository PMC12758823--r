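fx <- load_paper_fixtures()

test_that("membership schemes anchor triangular terms on the training range", {
  X <- tibble::tibble(a = c(0, 10))
  sch <- fit_membership_scheme(X, 3)
  mu0 <- membership_degrees(sch, "a", 0)
  expect_equal(mu0[1, ], c(Low = 1, Medium = 0, High = 0))
  expect_equal(membership_degrees(sch, "a", 5)[1, ],
               c(Low = 0, Medium = 1, High = 0))
  expect_equal(membership_degrees(sch, "a", 10)[1, ],
               c(Low = 0, Medium = 0, High = 1))
  expect_equal(membership_degrees(sch, "a", 2.5)[1, ],
               c(Low = 0.5, Medium = 0.5, High = 0))

  # argmax memberships reproduce a direct piecewise-linear oracle
  set.seed(31)
  for (rep in 1:5) {
    r <- sort(runif(2, -50, 50)); x <- runif(20, r[1], r[2])
    sch2 <- fit_membership_scheme(tibble::tibble(v = r), 3)
    mu <- membership_degrees(sch2, "v", x)
    mid <- mean(r)
    oracle <- cbind(
      Low = pmax(1 - (x - r[1]) / (mid - r[1]), 0),
      Medium = ifelse(x <= mid, (x - r[1]) / (mid - r[1]), (r[2] - x) / (r[2] - mid)),
      High = pmax((x - mid) / (r[2] - mid), 0)
    )
    expect_equal(mu, oracle, tolerance = 1e-9, ignore_attr = TRUE)
    # every in-range value has positive total membership
    expect_true(all(rowSums(mu) > 0))
  }

  expect_warning(fit_membership_scheme(tibble::tibble(c1 = rep(2, 5)), 3),
                 "constant attribute")
})

test_that("rule generation takes argmax terms, merges duplicates, resolves conflicts", {
  sch <- fit_membership_scheme(tibble::tibble(a = c(0, 10), b = c(0, 10)), 3)
  one <- generate_frb(tibble::tibble(a = 9.5, b = 0.2), y = "1", scheme = sch)
  expect_equal(nrow(one), 1)
  expect_equal(one$a, "High"); expect_equal(one$b, "Low")

  two <- generate_frb(tibble::tibble(a = c(9.5, 9.5), b = c(0.2, 0.2)),
                      y = c("1", "1"), scheme = sch)
  expect_equal(nrow(two), 1)
  expect_equal(two$weight, 2)

  # 20 records with a planted term-label pattern vs a hash-and-count oracle
  set.seed(32)
  X <- tibble::tibble(a = runif(20, 0, 10), b = runif(20, 0, 10))
  y <- ifelse(X$a > 5, "1", "0")
  frb <- generate_frb(X, y, scheme = sch)
  term_of <- function(x) c("Low", "Medium", "High")[
    max.col(cbind(pmax(1 - x / 5, 0),
                  ifelse(x <= 5, x / 5, (10 - x) / 5),
                  pmax((x - 5) / 5, 0)), ties.method = "first")]
  key <- paste(term_of(X$a), term_of(X$b), y)
  counts <- table(key)
  got_key <- paste(frb$a, frb$b, frb$label)
  # every surviving rule's weight is at least the oracle count for its signature+label
  # (conflict resolution may merge away lower-weight conflicting labels)
  expect_true(all(got_key %in% names(counts)))
  expect_equal(sort(unname(frb$weight[order(got_key)])),
               sort(unname(as.numeric(counts[sort(got_key)]))))
  # antecedents are unique after conflict resolution
  expect_false(anyDuplicated(paste(frb$a, frb$b)) > 0)

  expect_error(generate_frb(tibble::tibble(a = numeric()), y = character(), scheme = sch),
               class = "fkgmm_empty_frb")
})

test_that("the knowledge graph weights match hand counts on the 6-rule base", {
  g <- build_fkg(fx$table1_frb)
  # High1 appears in R2 and R5, both label 2
  expect_equal(unname(g$B["X1=High", "2"]), 1)
  expect_equal(unname(g$B["X1=High", "1"]), 0)
  # Low2 co-occurs with Low3 in R2 and R6 out of 6 rules
  expect_equal(unname(g$A["X2=Low", "X3=Low"]), 2 / 6)
  # structural invariants
  expect_equal(g$A, t(g$A))
  expect_true(all(g$A >= 0 & g$A <= 1))
  expect_true(all(g$B >= 0 & g$B <= 1))
  expect_equal(unname(rowSums(g$B)), rep(1, nrow(g$B)), tolerance = 1e-9)
  # same-attribute vertices never connect
  for (a in unique(g$V$attribute)) {
    idx <- which(g$V$attribute == a)
    expect_true(all(g$A[idx, idx] == 0))
  }

  # single-rule base: every antecedent vertex is one-hot on its label
  g1 <- build_fkg(as_frb(tibble::tibble(a = "Low", b = "High", label = "7")))
  expect_true(all(g1$B[, "7"] == 1))
})

test_that("graph sampling obeys the ceiling size law and reports a verifiable error", {
  # size law over rule-base sizes 1..30 at several rates
  for (n in c(1, 2, 3, 7, 13, 30)) {
    frb <- random_frb(n, seed = n)
    g <- build_fkg(frb)
    for (rate in c(0.1, 0.3, 0.5, 0.9, 1)) {
      s <- suppressWarnings(sample_fkgs(g, rate, error_threshold = Inf, seed = 1, max_iters = 1))
      expect_equal(nrow(s$frb), ceiling(rate * n))
      expect_true(all(s$frb$rule %in% frb$rule))
    }
  }

  # rate 1: the sample is the full graph with zero error
  g <- build_fkg(random_frb(12, seed = 40))
  s1 <- sample_fkgs(g, 1, 0.5, seed = 2)
  expect_equal(s1$achieved_error, 0)
  expect_equal(s1$B, g$B)

  # reported error equals an independent recomputation on the returned subset
  g10 <- build_fkg(random_frb(10, seed = 41))
  s <- suppressWarnings(sample_fkgs(g10, 0.5, 0, seed = 3, max_iters = 5))
  sub_frb <- g10$frb[g10$frb$rule %in% s$rule_ids, ]
  g_sub <- build_fkg(as_frb(tibble::as_tibble(sub_frb)))
  err <- mean(abs(g_sub$B[rownames(g_sub$B), colnames(g_sub$B)] -
                    {
                      Bf <- matrix(0, nrow(g_sub$B), ncol(g_sub$B),
                                   dimnames = dimnames(g_sub$B))
                      cl <- intersect(colnames(g_sub$B), colnames(g10$B))
                      Bf[, cl] <- g10$B[rownames(g_sub$B), cl]
                      Bf
                    }))
  expect_equal(s$achieved_error, err, tolerance = 1e-12)
})

test_that("fuzzy inference scores labels additively and handles ties and abstention", {
  # single rule at the term peaks: score 2 for its label
  sch <- fit_membership_scheme(tibble::tibble(a = c(0, 10), b = c(0, 10)), 3)
  frb1 <- generate_frb(tibble::tibble(a = 5, b = 10), y = "1", scheme = sch)
  g1 <- build_fkg(frb1)
  p <- fisa_classify(g1, tibble::tibble(a = 5, b = 10))
  expect_equal(p$.pred, "1")
  expect_equal(p$score_1, 2)

  # crisp record on the 6-rule base: hand-counted B gives 2.5 vs 0.5, label 1
  g <- build_fkg(fx$table1_frb)
  p2 <- fisa_classify(g, tibble::tibble(X1 = "Medium", X2 = "High", X3 = "High"))
  expect_equal(p2$.pred, "1")
  expect_equal(p2$score_1, 2.5) # Medium1 splits 1/2 across labels; High2, High3 pure
  expect_equal(p2$score_2, 0.5)

  # mirrored rules make both labels tie: the smaller label id wins
  mir <- as_frb(tibble::tibble(a = c("Low", "High"), b = c("High", "Low"),
                               label = c("2", "1")))
  gm <- build_fkg(mir)
  pt <- fisa_classify(gm, tibble::tibble(a = "Low", b = "Low"))
  expect_equal(pt$score_1, pt$score_2)
  expect_equal(pt$.pred, "1")

  expect_error(fisa_classify(gm, tibble::tibble(a = "Nope", b = "Nah")),
               class = "fkgmm_abstain_error")

  # separable rule bases classify their own training records perfectly
  set.seed(33)
  Xs <- tibble::tibble(u = c(runif(20, 0, 2), runif(20, 8, 10)),
                       v = c(runif(20, 8, 10), runif(20, 0, 2)))
  ys <- rep(c("1", "0"), each = 20)
  schs <- fit_membership_scheme(Xs, 3)
  gs <- build_fkg(generate_frb(Xs, ys, scheme = schs))
  preds <- fisa_classify(gs, Xs, scheme = schs)
  expect_equal(mean(preds$.pred == ys), 1)

  # a full-rate sample predicts identically to the full graph
  s_full <- sample_fkgs(gs, 1, 0, seed = 4)
  preds2 <- fisa_classify(s_full, Xs, scheme = schs)
  expect_equal(preds2$.pred, preds$.pred)
})

test_that("rule bases and graphs round-trip through CSV and JSON", {
  frb <- fx$table2_frb
  p <- withr::local_tempfile(fileext = ".csv")
  write_frb_csv(frb, p)
  back <- read_frb_csv(p)
  expect_equal(nrow(back), 14)
  expect_equal(back$Outlook, frb$Outlook)
  expect_equal(back$label, frb$label)
  expect_equal(attr(back, "attributes"), attr(frb, "attributes"))

  g <- build_fkg(frb)
  pj <- withr::local_tempfile(fileext = ".json")
  write_fkg_json(g, pj)
  g2 <- read_fkg_json(pj)
  expect_equal(g2$A, g$A, tolerance = 1e-12)
  expect_equal(g2$B, g$B, tolerance = 1e-12)
  expect_equal(g2$L, g$L)

  # broom-style accessors
  td <- tidy(g)
  expect_true(all(c("vertex", "attribute", "term", "label", "weight") %in% names(td)))
  expect_equal(nrow(glance(g)), 1)
})
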