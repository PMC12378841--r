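# Small in-code fixtures shared across test files.

toy_counts_matrix <- function() {
  m <- matrix(c(2, 3, 5,
                0, 4, 6), nrow = 3,
              dimnames = list(c("spA", "spB", "spC"), c("s1", "s2")))
  m
}

# hand-built 2-donor / 2-recipient study over a 4-visit schedule, with
# species chosen so that every origin occurs
toy_schedule <- function() {
  data.frame(timepoint = c("pre_fmt", "post_1", "post_2", "week_8"),
             week = c(0, 1, 2, 5), stringsAsFactors = FALSE)
}

toy_study <- function() {
  taxa <- c("sp_res", "sp_shared", "sp_don", "sp_nov", "sp_rare")
  sch <- toy_schedule()
  subjects <- data.frame(
    subject_id = c("D1", "D2", "P1", "P2"),
    role = c("donor", "donor", "recipient", "recipient"),
    donor_id = c(NA, NA, "D1", "D2"),
    response = c("unknown", "unknown", "responder", "non_responder"),
    sex = c(NA, NA, "female", "male"),
    pretreatment = c(NA, NA, "placebo", "budesonide"),
    age = c(NA, NA, 41, 55), stringsAsFactors = FALSE)
  sample_map <- data.frame(
    sample_id = c("D1_a", "D1_b", "D2_a",
                  "P1_pre", "P1_p1", "P1_p2", "P1_w8",
                  "P2_pre", "P2_p1", "P2_w8"),  # P2 misses post_2
    subject_id = c("D1", "D1", "D2", rep("P1", 4), rep("P2", 3)),
    timepoint = c(NA, NA, NA, "pre_fmt", "post_1", "post_2", "week_8",
                  "pre_fmt", "post_1", "week_8"), stringsAsFactors = FALSE)
  design <- study_design(subjects, sample_map, sch)
  counts <- rbind(
    #        D1_a D1_b D2_a P1pre P1p1 P1p2 P1w8 P2pre P2p1 P2w8
    sp_res    = c(0,   0,   0,  50,  40,  45,  42,  30,   0,  35),
    sp_shared = c(20,  15,  25,  30,  20,  25,  22,  40,  35,  30),
    sp_don    = c(30,  35,  20,   0,  35,   0,   0,   0,  20,  25),
    sp_nov    = c(0,   0,   0,   0,   0,  25,  30,   0,   0,   5),
    sp_rare   = c(1,   1,   1,  20,   5,   5,   6,  30,   5,   5))
  colnames(counts) <- sample_map$sample_id
  pm <- profile_matrix(counts)
  list(profile = pm, design = design, schedule = sch)
}

# scaled-down simulation config for fast unit tests
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_recipients = 6, n_responders = 3,
             donor_core_sizes = c(40, 30), donor_n_samples = c(4, 5),
             donor_background = 40, n_species_pool = 200,
             sequencing_depth = 2e4,
             n_resident = c(responder = 60, non_responder = 45), ...)
}

# random single-donor relative profile for core-set property tests
random_donor_design <- function(n_species, n_samples) {
  subjects <- data.frame(subject_id = "D", role = "donor",
                         donor_id = NA, response = "unknown", sex = NA,
                         pretreatment = NA, age = NA,
                         stringsAsFactors = FALSE)
  sample_map <- data.frame(sample_id = paste0("s", seq_len(n_samples)),
                           subject_id = "D", timepoint = NA,
                           stringsAsFactors = FALSE)
  study_design(subjects, sample_map, toy_schedule())
}

random_donor_profile <- function(n_species = 80, n_samples = 6) {
  m <- matrix(stats::rlnorm(n_species * n_samples, -5, 2.5),
              nrow = n_species,
              dimnames = list(sprintf("sp%03d", seq_len(n_species)),
                              paste0("s", seq_len(n_samples))))
  # sparsify so many species are absent from many samples
  m[stats::runif(length(m)) < 0.4] <- 0
  profile_matrix(m)
}

# quick path from simulated study to assignments/counts
categorize_sim <- function(sim, variant = "base",
                           shared_policy = "recipient_priority") {
  rel <- to_relative_abundance(sim$profile)
  presence <- call_presence(rel, sim$design)
  donors <- sim$design$subjects$subject_id[sim$design$subjects$role == "donor"]
  cores <- sapply(donors, function(d) extract_core_set(rel, sim$design, d),
                  simplify = FALSE)
  ca <- categorize_study(presence, cores, sim$design, variant, shared_policy)
  list(rel = rel, presence = presence, cores = cores, ca = ca,
       design = sim$design)
}
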