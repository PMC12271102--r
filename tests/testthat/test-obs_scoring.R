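test_that("MET score follows frequency x duration x MET value", {
  # empty record list
  expect_equal(compute_met(data.frame(activity_class = character(0),
                                      sessions = numeric(0),
                                      minutes = numeric(0))), 0)
  # printed-formula case: 3 sessions x 40 min x MET 4.0
  one <- data.frame(activity_class = "moderate", sessions = 3, minutes = 40)
  expect_equal(compute_met(one), 480)

  # randomized record lists vs an explicit loop oracle
  set.seed(101)
  for (i in 1:10) {
    k <- sample(1:8, 1)
    rec <- data.frame(
      participant_id = sample(c("a", "b"), k, replace = TRUE),
      activity_class = sample(c("transport", "moderate"), k, replace = TRUE),
      sessions = sample(0:7, k, replace = TRUE),
      minutes = round(runif(k, 0, 90)))
    mv <- c(transport = 3.5, moderate = 4.2)
    got <- compute_met(rec, mv)
    for (id in unique(rec$participant_id)) {
      expected <- 0
      for (j in which(rec$participant_id == id)) {
        expected <- expected + rec$sessions[j] * rec$minutes[j] *
          mv[[rec$activity_class[j]]]
      }
      expect_equal(got$met_total[got$participant_id == id], expected)
    }
  }

  expect_error(compute_met(data.frame(activity_class = "vigorous",
                                      sessions = 1, minutes = 10)),
               "vigorous")
  expect_error(compute_met(data.frame(activity_class = "moderate",
                                      sessions = -1, minutes = 10)),
               ">= 0")
})

test_that("alcohol scoring applies gender thresholds and boundaries", {
  # non-drinkers score 2 regardless of gender
  expect_equal(score_alcohol(0, "female"), 2L)
  expect_equal(score_alcohol(0, "male"), 2L)
  # 20 g/d is heavy for females, non-heavy for males
  expect_equal(score_alcohol(20, "female"), 0L)
  expect_equal(score_alcohol(20, "male"), 1L)
  # boundary: >= 15 (female) / >= 30 (male) is heavy
  expect_equal(score_alcohol(15, "female"), 0L)
  expect_equal(score_alcohol(30, "male"), 0L)
  expect_equal(score_alcohol(14.9, "female"), 1L)
  expect_equal(score_alcohol(29.9, "male"), 1L)
  expect_error(score_alcohol(-1, "male"), ">= 0")
})

test_that("gender tertile scores match direction and a brute-force oracle", {
  g <- rep("female", 9)
  expect_equal(gender_tertile_scores(1:9, g, "antioxidant"),
               rep(0:2, each = 3))
  expect_equal(gender_tertile_scores(1:9, g, "pro-oxidant"),
               rep(2:0, each = 3))

  # ties straddling a cutpoint all take the lower tertile's score
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    vals <- sample(1:8, n, replace = TRUE)  # heavy ties
    gen <- sample(c("male", "female"), n, replace = TRUE)
    if (min(table(gen)) < 3) next
    for (dir in c("antioxidant", "pro-oxidant")) {
      expect_equal(gender_tertile_scores(vals, gen, dir),
                   oracle_tertile(vals, gen, dir))
    }
  }

  # degenerate stratum: all identical -> everyone scores 1, loudly
  vals <- c(rep(5, 4), 1, 2, 3)
  gen <- c(rep("male", 4), rep("female", 3))
  expect_warning(sc <- gender_tertile_scores(vals, gen, "antioxidant"),
                 "identical")
  expect_equal(sc[1:4], rep(1L, 4))

  expect_error(gender_tertile_scores(1:4, c("male", "male", "female",
                                            "female"), "antioxidant"),
               ">= 3")
})

test_that("compute_obs sums components into lifestyle/dietary/total OBS", {
  an <- make_analysis(synthetic_config(n = 300, seed = 5))
  obs <- an$obs

  expect_true(all(obs$lifestyle_obs >= 0 & obs$lifestyle_obs <= 8))
  expect_true(all(obs$dietary_obs >= 0 & obs$dietary_obs <= 32))
  expect_true(all(obs$total_obs >= 0 & obs$total_obs <= 40))
  expect_equal(obs$total_obs, obs$lifestyle_obs + obs$dietary_obs)

  score_cols <- grep("^score_", names(obs), value = TRUE)
  expect_length(score_cols, 20)
  for (cl in score_cols) expect_true(all(obs[[cl]] %in% 0:2))

  # per-gender tertile components split the stratum roughly in thirds
  for (g in c("male", "female")) {
    sel <- an$cohort$gender == g
    for (cl in c("score_fiber", "score_iron", "score_bmi")) {
      shares <- tabulate(obs[[cl]][sel] + 1L, 3) / sum(sel)
      expect_true(all(abs(shares - 1 / 3) < 0.02), label = paste(g, cl))
    }
  }

  # registry must cover all 20 default components
  reg <- component_registry()
  expect_error(compute_obs(an$cohort, registry = reg[-1, ]), "20")
})

test_that("a participant at the antioxidant-favourable extreme scores the maximum", {
  df <- make_mini_cohort(n = 12)
  # make participant 1 (male) the antioxidant extreme of their stratum:
  # highest on every antioxidant, lowest on every pro-oxidant, non-drinker
  males <- df$gender == "male"
  for (v in dietary_components()) {
    df[[v]][males][1] <- if (v %in% c("total_fat", "iron"))
      min(df[[v]][males]) - 1 else max(df[[v]][males]) + 1
  }
  df$bmi[males][1] <- min(df$bmi[males]) - 1
  df$cotinine[males][1] <- min(df$cotinine[males]) - 0.001
  df$alcohol <- 0
  df$pa_moderate_sessions[males][1] <- 7
  df$pa_moderate_minutes[males][1] <- 600
  obs <- compute_obs(cohort_table(df))
  id <- df$participant_id[males][1]
  row <- obs[obs$participant_id == id, ]
  expect_equal(row$lifestyle_obs, 8L)
  expect_equal(row$dietary_obs, 32L)
  expect_equal(row$total_obs, 40L)
})

test_that("scores are permutation invariant and direction monotone", {
  an <- make_analysis(synthetic_config(n = 120, seed = 9))
  perm <- sample(nrow(an$cohort))
  shuffled <- an$cohort[perm, ]
  class(shuffled) <- class(an$cohort)
  obs2 <- compute_obs(shuffled)
  m <- match(an$obs$participant_id, obs2$participant_id)
  expect_equal(obs2$total_obs[m], an$obs$total_obs)
  expect_equal(obs2$lifestyle_obs[m], an$obs$lifestyle_obs)

  # monotonicity at fixed cutpoints: raising an antioxidant value never
  # lowers its score; pro-oxidant components are anti-monotone
  v <- an$cohort$fiber
  g <- an$cohort$gender
  s0 <- gender_tertile_scores(v, g, "antioxidant")
  cuts <- tapply(v, g, quantile, probs = c(1, 2) / 3, type = 7)
  v2 <- v
  v2[1] <- v[1] + diff(range(v))  # push participant 1 upward
  s1 <- ifelse(v2[1] <= cuts[[g[1]]][1], 0L,
               ifelse(v2[1] <= cuts[[g[1]]][2], 1L, 2L))
  expect_gte(s1, s0[1])
  p0 <- gender_tertile_scores(v, g, "pro-oxidant")
  expect_lte(2L - s1, p0[1])
})

test_that("median_split puts the median itself in the low group", {
  s <- median_split(c(10, 13, 16))
  expect_equal(as.character(s), c("low", "low", "high"))
  expect_equal(attr(s, "median"), 13)

  # all-equal values: everyone low
  expect_true(all(median_split(rep(4, 5)) == "low"))

  # group sizes match a sort-based oracle
  set.seed(3)
  for (i in 1:10) {
    n <- sample(c(49, 50), 1)
    x <- sample(0:8, n, replace = TRUE)
    s <- median_split(x)
    srt <- sort(x)
    m_oracle <- if (n %% 2) srt[(n + 1) / 2]
                else (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(sum(s == "low"), sum(x <= m_oracle))
  }
})
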