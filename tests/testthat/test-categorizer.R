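test_that("worked series follow the decision rules", {
  # donor species: colonises, two absences (tolerated NA then Rejection),
  # then re-detected as Donor transient
  expect_equal(categorize_series("donor", c(1, 0, 0, 1), "base"),
               c("Colonisation", NA, "Rejection", "Donor transient"))
  # no absences: stable throughout, for every variant
  for (v in c("base", "s1", "s2", "s3", "s4"))
    expect_equal(categorize_series("recipient", rep(1, 5), v),
                 rep("Resident", 5))
  # single tolerated absence: base returns to Resident, s1 treats it as loss
  expect_equal(categorize_series("recipient", c(1, 0, 1), "base"),
               c("Resident", NA, "Resident"))
  expect_equal(categorize_series("recipient", c(1, 0, 1), "s1"),
               c("Resident", "Species loss", "Recipient transient"))
  # novel species: NA before first detection; missing visits skipped
  expect_equal(categorize_series("novel", c(0, NA, 1, 1), "base"),
               c(NA, NA, "Novel", "Novel"))
  # s2 memory: presence after presence returns to stable even after a loss
  expect_equal(categorize_series("donor", c(1, 0, 0, 1, 1), "s2"),
               c("Colonisation", NA, "Rejection", "Donor transient",
                 "Colonisation"))
  # s3/s4 retrospective: any disallowed absence makes presences transient
  expect_equal(categorize_series("recipient", c(1, 0, 1), "s4"),
               c("Recipient transient", "Species loss",
                 "Recipient transient"))
  expect_equal(categorize_series("recipient", c(1, 0, 1), "s3"),
               c("Resident", NA, "Resident"))
  expect_error(categorize_series("donor", integer(0)), "empty")
  expect_error(categorize_series("donor", c(1, 0), "s9"), "unknown")
})

test_that("state machine matches the brute-force oracle on random patterns", {
  set.seed(402)
  for (i in 1:150) {
    len <- sample(3:9, 1)
    st <- sample(c(0L, 1L, NA), len, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
    origin <- sample(c("recipient", "donor", "novel"), 1)
    v <- sample(c("base", "s1", "s2", "s3", "s4"), 1)
    expect_identical(categorize_series(origin, st, v),
                     oracle_categorize(origin, st, v),
                     label = paste(origin, v, paste(st, collapse = "")))
  }
})

test_that("origin assignment respects pre-FMT presence, core sets and shared policy", {
  toy <- toy_study()
  rel <- to_relative_abundance(toy$profile)
  pres <- call_presence(rel, toy$design)
  core1 <- extract_core_set(rel, toy$design, "D1")
  expect_setequal(core1$species, c("sp_shared", "sp_don", "sp_rare"))
  uni <- build_universe("P1", pres, core1)
  # present pre-FMT and in core: recipient under the default policy
  expect_equal(unname(uni["sp_shared"]), "recipient")
  expect_equal(unname(uni["sp_res"]), "recipient")
  # absent pre-FMT, in core: donor; absent in both, appears later: novel
  expect_equal(unname(uni["sp_don"]), "donor")
  expect_equal(unname(uni["sp_nov"]), "novel")
  # donor-priority reassigns shared species
  uni2 <- build_universe("P1", pres, core1, shared_policy = "donor_priority")
  expect_equal(unname(uni2["sp_shared"]), "donor")
  expect_equal(unname(uni2["sp_res"]), "recipient")
  # origins never change over time within a study run
  ca <- categorize_study(pres, list(D1 = core1,
                                    D2 = extract_core_set(rel, toy$design, "D2")),
                         toy$design)
  per_pair <- tapply(ca$origin, paste(ca$recipient, ca$species),
                     function(x) length(unique(x)))
  expect_true(all(per_pair == 1))
  # core donor mismatch errors
  expect_error(categorize_study(pres, list(D1 = core1, D2 = core1),
                                toy$design), "mismatch")
})

test_that("study-level categorisation is complete, deterministic and countable", {
  sim <- simulate_study(tiny_sim_config(seed = 3))
  run <- categorize_sim(sim)
  ca <- run$ca
  # one row per (recipient, universe species, observed timepoint)
  for (r in unique(ca$recipient)) {
    sub <- ca[ca$recipient == r, ]
    n_species <- length(unique(sub$species))
    n_tp <- length(unique(sub$timepoint))
    expect_equal(nrow(sub), n_species * n_tp)
  }
  # determinism
  ca2 <- categorize_sim(sim)$ca
  expect_identical(ca, ca2)
  # partition: counts + NA = universe size at every observed slot
  cnt <- count_by_category(ca)
  na_cnt <- attr(cnt, "na_counts")
  tot <- stats::aggregate(n ~ recipient + timepoint, cnt, sum)
  m <- merge(tot, na_cnt, by = c("recipient", "timepoint"))
  uni_size <- tapply(ca$species, ca$recipient,
                     function(x) length(unique(x)))
  expect_true(all(m$n + m$n_na == uni_size[m$recipient]))
  # category labels always agree with the origin triplet
  cats <- ecological_categories()
  ok <- is.na(ca$category) |
    (ca$category == cats[ca$origin, "stable"]) |
    (ca$category == cats[ca$origin, "transient"]) |
    (ca$category == cats[ca$origin, "loss"])
  expect_true(all(ok))
  # mixed variants are rejected by the counter
  expect_error(count_by_category(rbind(ca, within(ca, variant <- "s1"))),
               "variant")
})

test_that("hand-tallied toy counts match count_by_category", {
  toy <- toy_study()
  run <- list()
  rel <- to_relative_abundance(toy$profile)
  pres <- call_presence(rel, toy$design)
  cores <- list(D1 = extract_core_set(rel, toy$design, "D1"),
                D2 = extract_core_set(rel, toy$design, "D2"))
  ca <- categorize_study(pres, cores, toy$design)
  cnt <- count_by_category(ca)
  pick <- function(r, tp, cat)
    cnt$n[cnt$recipient == r & cnt$timepoint == tp & cnt$category == cat]
  # P1: sp_res, sp_shared, sp_rare resident at pre_fmt; sp_don, sp_nov NA
  expect_equal(pick("P1", "pre_fmt", "Resident"), 3L)
  expect_equal(attr(cnt, "na_counts")$n_na[
    attr(cnt, "na_counts")$recipient == "P1" &
    attr(cnt, "na_counts")$timepoint == "pre_fmt"], 2L)
  # P1 post_1: sp_don colonises; sp_res/sp_shared/sp_rare still resident
  expect_equal(pick("P1", "post_1", "Colonisation"), 1L)
  expect_equal(pick("P1", "post_1", "Resident"), 3L)
  # P1 post_2: sp_don absent (tolerated NA), sp_nov detected
  expect_equal(pick("P1", "post_2", "Novel"), 1L)
  expect_equal(pick("P1", "post_2", "Colonisation"), 0L)
  # P1 week_8: sp_don second absence -> Rejection
  expect_equal(pick("P1", "week_8", "Rejection"), 1L)
  # P2 (missed post_2): sp_res absent at post_1 (tolerated), back at week_8
  expect_equal(pick("P2", "week_8", "Resident"), 3L)
})

test_that("family distribution counts distinct species once per category", {
  toy <- toy_study()
  rel <- to_relative_abundance(toy$profile)
  pres <- call_presence(rel, toy$design)
  cores <- list(D1 = extract_core_set(rel, toy$design, "D1"),
                D2 = extract_core_set(rel, toy$design, "D2"))
  ca <- categorize_study(pres, cores, toy$design)
  tax <- c(sp_res = "famA", sp_shared = "famA", sp_don = "famB")
  fd <- family_category_distribution(ca, tax)
  # sp_don for P1 is Colonisation then Rejection: one species in each column
  gb <- function(f, cat) fd$n_species[fd$family == f & fd$category == cat]
  expect_equal(gb("famB", "Colonisation"), 1L)
  expect_equal(gb("famB", "Rejection"), 1L)
  # species without taxonomy fall into "unclassified"
  expect_true("unclassified" %in% fd$family)
  # empty taxonomy: everything unclassified
  fd0 <- family_category_distribution(ca, character())
  expect_setequal(unique(fd0$family), "unclassified")
})
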