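test_that("designed pairs realise each inter-trial condition", {
  # TP with a green-distractor current trial: all-red preview, then
  # red-target/green-distractor search
  tp <- build_pair("TP", "green")
  expect_equal(tp$target_present, c(FALSE, TRUE))
  expect_equal(tp$distractor_color, c("red", "green"))
  expect_equal(tp$target_color, c(NA, "red"))
  # DP: preview in the current distractors' colour
  dp <- build_pair("DP", "green")
  expect_equal(dp$target_present, c(FALSE, TRUE))
  expect_equal(dp$distractor_color, c("green", "green"))
  # SSw: swapped assignment on the first trial
  ssw <- build_pair("SSw", "green")
  expect_equal(ssw$target_present, c(TRUE, TRUE))
  expect_equal(ssw$target_color, c("green", "red"))
  expect_equal(ssw$distractor_color, c("red", "green"))
  # SRe: identical displays
  sre <- build_pair("SRe", "red")
  expect_identical(unlist(sre[1, ]), unlist(sre[2, ]))
})

test_that("every designed pair classifies as its own condition", {
  for (cond in conditions()) {
    for (col in c("red", "green")) {
      pr <- build_pair(cond, col)
      pr$subject <- 1; pr$session <- 1; pr$block <- 1
      lab <- classify_trials(pr)$condition
      expect_identical(lab[2], cond)
    }
  }
})

test_that("a 32-trial set has the designed composition", {
  set.seed(3)
  for (i in 1:20) {
    st <- build_set()
    expect_identical(nrow(st), 32L)
    designed <- st[!is.na(st$pair_condition), ]
    expect_identical(nrow(designed), 16L)
    expect_identical(sum(designed$target_present), 12L)
    expect_identical(sum(!designed$target_present), 4L)
    inserted <- st[is.na(st$pair_condition), ]
    expect_identical(sum(!inserted$target_present), 8L)
    expect_equal(as.vector(table(inserted$distractor_color)), c(8, 8))
    # pairs are never split: role 1 is always immediately followed by role 2
    i1 <- which(st$pair_role == 1L)
    expect_true(all(st$pair_role[i1 + 1L] == 2L))
    expect_true(all(st$pair_condition[i1 + 1L] == st$pair_condition[i1]))
    # colour invariants
    pres <- st[st$target_present, ]
    expect_true(all(pres$target_color != pres$distractor_color))
    expect_true(all(is.na(st$target_color[!st$target_present])))
  }
})

test_that("the default study yields 1600 trials per subject, deterministically", {
  d <- build_study(n_subjects = 2, seed = 10)
  expect_identical(nrow(d), 3200L)
  expect_equal(as.vector(table(d$subject)), c(1600, 1600))
  one <- build_study(n_subjects = 1, sessions = 1, seed = 2)
  expect_identical(nrow(one), 320L)
  # seeded determinism; different seeds permute but keep marginal counts
  expect_identical(build_study(n_subjects = 1, seed = 4),
                   build_study(n_subjects = 1, seed = 4))
  d1 <- build_study(n_subjects = 1, seed = 5)
  d2 <- build_study(n_subjects = 1, seed = 6)
  expect_false(identical(d1, d2))
  expect_identical(sum(d1$target_present), sum(d2$target_present))
  expect_error(build_study(trials_per_block = 48), "multiple of 32")
})

test_that("classification follows the preceding trial and stops at block boundaries", {
  seqs <- data.frame(
    subject = 1, session = 1, block = c(1, 1, 1, 1, 2),
    target_present = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    target_color = c("red", "red", NA, "green", "red"),
    distractor_color = c("green", "green", "green", "red", "green"))
  lab <- classify_trials(seqs)$condition
  # trial 2 repeats trial 1; trial 4 follows an all-green absent display
  # with a green target; trial 5 opens a new block
  expect_identical(lab, c("unlabeled", "SRe", "absent", "TP", "unlabeled"))

  set.seed(12)
  d <- classify_trials(build_study(n_subjects = 1, sessions = 2))
  firsts <- d[!duplicated(d[c("session", "block")]), ]
  expect_true(all(firsts$condition %in% c("unlabeled", "absent")))
  # every labelled condition occurs in quantity
  expect_true(all(table(d$condition[d$condition %in% conditions()]) > 20))
})

test_that("trial tables round-trip through the CSV dialect", {
  m <- reference_full_params("P2")
  d <- generate_study(list(m), sessions = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials(d, path)
  d2 <- read_trials(path)
  expect_equal(d2$latency, d$latency, tolerance = 1e-9)
  expect_identical(d2$correct, d$correct)
  expect_identical(d2$target_present, d$target_present)
  expect_identical(d2$condition, d$condition)
})
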