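mk_map <- function(val, level = "trial", n_v = NA_integer_) {
  frequency_map(matrix(val, 2, 4), c(0, 4, 8, 12), c("Cz", "Pz"),
                level = level, n_v = n_v)
}

test_that("trial maps combine by cellwise mean", {
  m1 <- mk_map(1); m0 <- mk_map(0)
  expect_true(all(combine_trials(list(m1, m1)) == 1))
  expect_true(all(combine_trials(list(m1, m0)) == 0.5))
  expect_true(all(abs(combine_trials(list(m1, m1, m0)) - 2 / 3) < 1e-15))
  expect_identical(attr(combine_trials(list(m1, m0)), "level"), "subject")
  bad <- frequency_map(matrix(0, 3, 4), c(0, 4, 8, 12), c("a", "b", "c"))
  expect_error(combine_trials(list(m1, bad)), "mismatched axes")
})

test_that("subjects are combined with equal weight regardless of trial counts", {
  subjA <- combine_trials(replicate(5, mk_map(1), simplify = FALSE))
  subjB <- combine_trials(list(mk_map(0)))
  g <- combine_subjects(list(A = subjA, B = subjB))
  expect_true(all(g == 0.5))        # not 5/6
  expect_equal(attr(g, "n_s"), 2L)
  expect_equal(attr(g, "n_v"), 6L)
  single <- combine_subjects(list(A = subjA))
  expect_equal(unclass(single), unclass(subjA), ignore_attr = TRUE)
  expect_equal(unclass(combine_subjects(list(B = subjB, A = subjA))),
               unclass(g), ignore_attr = TRUE)  # order invariance
  expect_error(combine_subjects(list(subjA, subjB)), "named")
  expect_error(combine_subjects(stats::setNames(list(subjA, subjB), c("A", "A"))),
               "named")
})

test_that("duplicating a subject's trials never changes the group map", {
  set.seed(50)
  t1 <- mk_map(0); t1[] <- runif(8)
  t2 <- mk_map(0); t2[] <- runif(8)
  sA <- combine_trials(list(t1, t2))
  sA_dup <- combine_trials(list(t1, t2, t1, t2))
  sB <- mk_map(0.25)
  g1 <- combine_subjects(list(A = sA, B = sB))
  g2 <- combine_subjects(list(A = sA_dup, B = sB))
  expect_equal(unclass(g1), unclass(g2), ignore_attr = TRUE)
})

test_that("the decision tree categorizes Table 1 exemplar subjects correctly", {
  row <- function(id, cls, eeg, fmri, v = 1)
    data.frame(subject_id = id, visit_index = v, behavioural_class = cls,
               eeg_cf = eeg, fmri_cf = fmri)
  ps03 <- categorize_subject(row("PS03", "VS/UWS", "pos", "pos"))
  expect_equal(ps03$cf_status, "CF+")
  expect_equal(ps03$lp_status, "LP+")
  ps05 <- categorize_subject(row("PS05", "MCS+", "neg", "neg"))
  expect_equal(ps05$cf_status, "CF-")
  expect_equal(ps05$lp_status, "LP+")
  expect_identical(ps05$basis, "behavioural")
  ps04 <- categorize_subject(row("PS04", "VS/UWS", "neg", "neg"))
  expect_equal(ps04$cf_status, "CF-")
  expect_equal(ps04$lp_status, "LP-")
  hc <- categorize_subject(row("HC01", "HC", "not_done", "not_done"))
  expect_true(hc$is_hc)
  expect_true(is.na(hc$cf_status))
  # not_done contributes no evidence
  nd <- categorize_subject(row("PS17", "VS/UWS", "pos", "not_done"))
  expect_equal(nd$cf_status, "CF+")
  expect_error(categorize_subject(row("X", "COMA", "neg", "neg")),
               "behavioural class")
})

test_that("any-visit evidence drives subject-level categorization", {
  visits <- data.frame(subject_id = "PS01", visit_index = 1:2,
                       behavioural_class = c("MCS-", "MCS+"),
                       eeg_cf = c("neg", "pos"), fmri_cf = c("neg", "neg"))
  r <- categorize_subject(visits)
  expect_equal(r$cf_status, "CF+")
  expect_equal(r$per_visit$cf, c(FALSE, TRUE))
  expect_equal(r$per_visit$lp, c(FALSE, TRUE))
})

test_that("categorization is monotone in added positive evidence", {
  set.seed(51)
  meta <- read_subject_metadata(table1_path())
  ps_ids <- unique(meta$subject_id[meta$behavioural_class != "HC"])
  for (id in sample(ps_ids, 8)) {
    rows <- meta[meta$subject_id == id, , drop = FALSE]
    before <- categorize_subject(rows)$lp_status
    rows$eeg_cf[1] <- "pos"
    after <- categorize_subject(rows)$lp_status
    expect_false(before == "LP+" && after == "LP-")
    expect_equal(after, "LP+")
  }
})

test_that("category tallies separate subject and visit levels", {
  meta <- data.frame(subject_id = c("S1", "S1", "S2"),
                     visit_index = c(1, 2, 1),
                     behavioural_class = c("VS/UWS", "VS/UWS", "MCS+"),
                     eeg_cf = c("pos", "neg", "neg"),
                     fmri_cf = c("neg", "neg", "neg"))
  ct <- count_categories(meta)
  expect_equal(unname(ct$subjects["CF+"]), 1)   # S1 counted once
  expect_equal(unname(ct$visits["CF+"]), 1)     # only visit 1 of S1
  expect_equal(unname(ct$subjects["LP+"]), 2)
  empty <- meta[0, , drop = FALSE]
  ct0 <- count_categories(empty)
  expect_true(all(ct0$subjects == 0))
  expect_true(all(ct0$visits == 0))
})

test_that("the cohort fixture reproduces the published category structure", {
  meta <- read_subject_metadata(table1_path())
  ct <- count_categories(meta)
  expect_equal(unname(ct$subjects["n_ps"]), 24)
  expect_equal(unname(ct$subjects["n_hc"]), 8)
  expect_equal(unname(ct$subjects["CF+"]), 16)
  expect_equal(unname(ct$subjects["LP+"]), 19)
  cats <- categorize_subjects(meta)
  ps <- cats[!cats$is_hc, ]
  # CF+ implies LP+
  expect_true(all(ps$lp_status[ps$cf_status == "CF+"] == "LP+"))
  # all MCS+/eMCS subjects are LP+
  beh_lp <- unique(meta$subject_id[meta$behavioural_class %in% c("MCS+", "eMCS")])
  expect_true(all(ps$lp_status[ps$subject_id %in% beh_lp] == "LP+"))
})
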