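#' The nine ecological categories
#'
#' Categories cross a species' origin (recipient-derived, donor-derived,
#' novel) with its temporal status (stable, transient/intermittent, previous
#' occupant/lost).
#'
#' @return character matrix, rows = origins, columns = temporal statuses.
#' @export
ecological_categories <- function() {
  m <- matrix(c("Resident",     "Recipient transient", "Species loss",
                "Colonisation", "Donor transient",     "Rejection",
                "Novel",        "Novel transient",     "Novel loss"),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("recipient", "donor", "novel"),
                              c("stable", "transient", "loss")))
  m
}

category_levels <- function() as.vector(t(ecological_categories()))

#' Categoriser variant definitions
#'
#' The base case tolerates one single absence per species (labelled NA) and
#' uses presence at all previous timepoints; the four sensitivity variants
#' switch the absence allowance off (`s1`, `s4`), restrict memory to the
#' previous observed timepoint (`s2`), or classify retrospectively from the
#' full series (`s3`, `s4`).
#'
#' @param variant one of `"base"`, `"s1"`, `"s2"`, `"s3"`, `"s4"`, or a list
#'   with fields `allow_single_absence` and `memory`.
#' @return list with `name`, `allow_single_absence`,
#'   `memory` (one of `"all_previous"`, `"previous_only"`, `"full_series"`).
#' @export
categorizer_variant <- function(variant = "base") {
  if (is.list(variant)) {
    stopifnot(is.logical(variant$allow_single_absence),
              variant$memory %in% c("all_previous", "previous_only",
                                    "full_series"))
    variant$name <- variant$name %||% "custom"
    return(variant)
  }
  switch(as.character(variant),
    base = list(name = "base", allow_single_absence = TRUE,  memory = "all_previous"),
    s1   = list(name = "s1",   allow_single_absence = FALSE, memory = "all_previous"),
    s2   = list(name = "s2",   allow_single_absence = TRUE,  memory = "previous_only"),
    s3   = list(name = "s3",   allow_single_absence = TRUE,  memory = "full_series"),
    s4   = list(name = "s4",   allow_single_absence = FALSE, memory = "full_series"),
    stop("unknown categoriser variant: ", variant)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_status_int <- function(statuses) {
  if (is.character(statuses)) {
    ok <- statuses %in% c("present", "absent", "missing")
    if (!all(ok)) stop("unknown status value: ", statuses[!ok][1])
    st <- ifelse(statuses == "present", 1L,
                 ifelse(statuses == "absent", 0L, NA_integer_))
  } else {
    st <- as.integer(statuses)
    if (!all(st %in% c(0L, 1L) | is.na(st)))
      stop("statuses must be 0/1/NA or present/absent/missing")
  }
  st
}

#' Categorise one species' presence series
#'
#' Assigns an ecological category (or NA) to every timepoint of a single
#' species in a single recipient, given its origin and ordered
#' presence/absence series. Missing visits (NA statuses) carry no information:
#' they receive NA and are skipped by the state logic, neither consuming the
#' tolerated absence nor triggering a loss.
#'
#' Under the base case, recipient-origin species are considered detected from
#' the start of the series; donor- and novel-origin species are NA until their
#' first detection, which is labelled with the stable category (Colonisation /
#' Novel). The first observed absence after detection is tolerated (NA) once
#' per species; any further absence (or any absence when the allowance is off)
#' is a loss category, repeated while the species stays absent. Once a loss
#' has been assigned, re-detection yields the transient category and the
#' species never returns to the stable category (`s2` excepted: with
#' previous-timepoint memory only, presence after presence is stable again).
#' Variants `s3`/`s4` classify retrospectively from the full series: all
#' present timepoints are stable only when no disallowed absence occurs
#' anywhere after first detection, otherwise present timepoints are transient
#' and post-detection absences are losses (first absence NA under `s3`).
#'
#' @param origin `"recipient"`, `"donor"` or `"novel"`.
#' @param statuses ordered vector over the schedule: 1/0/NA or
#'   "present"/"absent"/"missing".
#' @param variant see [categorizer_variant()].
#' @return character vector of categories, NA where uncategorised.
#' @export
categorize_series <- function(origin, statuses, variant = "base") {
  origin <- match.arg(origin, c("recipient", "donor", "novel"))
  v <- categorizer_variant(variant)
  st <- as_status_int(statuses)
  n <- length(st)
  if (n == 0) stop("empty status series")
  labs <- ecological_categories()[origin, ]
  out <- rep(NA_character_, n)
  obs <- which(!is.na(st))
  if (length(obs) == 0) return(out)

  if (v$memory == "full_series") {
    det <- if (origin == "recipient") obs[1] else {
      p <- obs[st[obs] == 1L]
      if (length(p) == 0) return(out) else p[1]
    }
    post <- obs[obs >= det]
    abs_post <- post[st[post] == 0L]
    tolerated <- if (v$allow_single_absence && length(abs_post) > 0)
      abs_post[1] else -1L
    disallowed <- abs_post[abs_post != tolerated]
    stable <- length(disallowed) == 0
    for (i in post) {
      out[i] <- if (st[i] == 1L) {
        if (stable) labs[["stable"]] else labs[["transient"]]
      } else if (i == tolerated) NA_character_ else labs[["loss"]]
    }
    return(out)
  }

  detected <- origin == "recipient"
  allowance_used <- FALSE
  lost_ever <- FALSE
  # s2: recipient-origin species carry an implicit pre-series presence
  prev <- 1L
  for (i in obs) {
    s <- st[i]
    if (!detected) {
      if (s == 1L) {
        detected <- TRUE
        out[i] <- labs[["stable"]]
      } # absent before first detection: NA, no allowance consumed
    } else if (v$memory == "previous_only") {
      if (s == 1L) {
        out[i] <- if (prev == 1L) labs[["stable"]] else labs[["transient"]]
      } else if (prev == 1L && v$allow_single_absence && !allowance_used) {
        allowance_used <- TRUE
      } else {
        out[i] <- labs[["loss"]]
      }
    } else { # all_previous (base, s1)
      if (s == 1L) {
        out[i] <- if (lost_ever) labs[["transient"]] else labs[["stable"]]
      } else if (v$allow_single_absence && !allowance_used) {
        allowance_used <- TRUE
      } else {
        out[i] <- labs[["loss"]]
        lost_ever <- TRUE
      }
    }
    prev <- s
  }
  out
}

#' Build a recipient's species universe and origins
#'
#' The universe for a recipient is every species ever present at any of the
#' recipient's timepoints, plus the core microbiota of the assigned donor.
#' Origin is fixed per (recipient, species): species present in any pre-FMT
#' sample are recipient-derived; otherwise species in the donor core are
#' donor-derived; the remainder are novel. Species present pre-FMT *and* in
#' the donor core are "shared": the default policy keeps them recipient-
#' derived, `"donor_priority"` reassigns them to the donor (sensitivity
#' analysis).
#'
#' @param recipient_id recipient subject id.
#' @param presence a `presence_matrix` from [call_presence()].
#' @param core the [extract_core_set()] of the recipient's assigned donor.
#' @param shared_policy `"recipient_priority"` (default) or `"donor_priority"`.
#' @param pre_fmt_timepoints labels of the pre-FMT reference visits; defaults
#'   to all scheduled visits with week <= 0 (baseline and pre-FMT samples).
#' @return named character vector species -> origin.
#' @export
build_universe <- function(recipient_id, presence, core,
                           shared_policy = c("recipient_priority",
                                             "donor_priority"),
                           pre_fmt_timepoints = NULL) {
  shared_policy <- match.arg(shared_policy)
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(core, "core_donor_set"))
  if (!recipient_id %in% dimnames(presence)[[3]])
    stop("recipient not in presence data: ", recipient_id)
  sch <- attr(presence, "schedule")
  if (is.null(pre_fmt_timepoints))
    pre_fmt_timepoints <- sch$timepoint[sch$week <= 0]
  slab <- dimnames(presence)[[1]]
  mat <- presence[, , recipient_id, drop = TRUE]
  ever <- rowSums(mat == 1L, na.rm = TRUE) > 0
  pre <- rowSums(mat[, pre_fmt_timepoints, drop = FALSE] == 1L,
                 na.rm = TRUE) > 0
  in_core <- slab %in% core$species
  universe <- slab[ever | in_core]
  pre_u <- pre[match(universe, slab)]
  core_u <- in_core[match(universe, slab)]
  origin <- ifelse(pre_u & !(shared_policy == "donor_priority" & core_u),
                   "recipient",
                   ifelse(core_u, "donor", "novel"))
  stats::setNames(origin, universe)
}

#' Categorise an entire study
#'
#' Runs [build_universe()] and [categorize_series()] for every recipient and
#' species, returning the long category assignment table.
#'
#' @param presence a `presence_matrix`.
#' @param cores named list donor_id -> [extract_core_set()] (one per donor).
#' @param design a [study_design].
#' @param variant categoriser variant (scalar) — see [categorizer_variant()].
#' @param shared_policy see [build_universe()].
#' @param pre_fmt_timepoints see [build_universe()].
#' @return data.frame with columns `recipient`, `species`, `timepoint`,
#'   `week`, `origin`, `category` (NA where uncategorised), `variant`,
#'   `shared_policy`; one row per (recipient, universe species, observed
#'   timepoint).
#' @export
categorize_study <- function(presence, cores, design, variant = "base",
                             shared_policy = "recipient_priority",
                             pre_fmt_timepoints = NULL) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(design, "study_design"))
  v <- categorizer_variant(variant)
  sch <- attr(presence, "schedule")
  subs <- design$subjects
  out <- vector("list", length(recipients(design)))
  k <- 0
  for (r in recipients(design)) {
    donor <- subs$donor_id[subs$subject_id == r]
    core <- cores[[donor]]
    if (is.null(core)) stop("no core set supplied for donor ", donor)
    if (core$donor_id != donor)
      stop("core set donor mismatch for recipient ", r, ": expected ", donor,
           ", got ", core$donor_id)
    origin <- build_universe(r, presence, core, shared_policy,
                             pre_fmt_timepoints)
    mat <- presence[, , r, drop = TRUE]
    observed <- which(!is.na(mat[1, ]))
    if (length(origin) == 0 || length(observed) == 0) next
    cats <- matrix(NA_character_, nrow = length(origin),
                   ncol = length(observed))
    for (j in seq_along(origin)) {
      full <- categorize_series(origin[j], mat[names(origin)[j], ], v)
      cats[j, ] <- full[observed]
    }
    k <- k + 1
    out[[k]] <- data.frame(
      recipient = r,
      species = rep(names(origin), times = length(observed)),
      timepoint = rep(sch$timepoint[observed], each = length(origin)),
      week = rep(sch$week[observed], each = length(origin)),
      origin = rep(unname(origin), times = length(observed)),
      category = as.vector(cats),
      stringsAsFactors = FALSE
    )
  }
  res <- if (k == 0) data.frame(recipient = character(), species = character(),
                                timepoint = character(), week = numeric(),
                                origin = character(), category = character())
         else do.call(rbind, out[seq_len(k)])
  res$variant <- v$name
  res$shared_policy <- shared_policy
  rownames(res) <- NULL
  res
}

#' Count species per ecological category
#'
#' Tallies the number of species in each of the nine categories per recipient
#' and timepoint. NA (uncategorised) rows are excluded from every category
#' count; unobserved categories appear with count zero so that downstream
#' models see a complete grid.
#'
#' @param ca category assignment table from [categorize_study()].
#' @return data.frame `recipient`, `timepoint`, `week`, `category`, `n`,
#'   with an `na_counts` attribute holding the per-(recipient, timepoint)
#'   number of NA-categorised species.
#' @export
count_by_category <- function(ca) {
  if (length(unique(ca$variant)) > 1)
    stop("mixed categoriser variants; select one before counting")
  lev <- category_levels()
  key <- unique(ca[, c("recipient", "timepoint", "week")])
  key <- key[order(key$recipient, key$week), ]
  tab <- table(
    interaction(ca$recipient, ca$timepoint, drop = FALSE, sep = "\r"),
    factor(ca$category, levels = lev)
  )
  ids <- paste(key$recipient, key$timepoint, sep = "\r")
  counts <- tab[ids, , drop = FALSE]
  res <- data.frame(
    recipient = rep(key$recipient, each = length(lev)),
    timepoint = rep(key$timepoint, each = length(lev)),
    week = rep(key$week, each = length(lev)),
    category = rep(lev, times = nrow(key)),
    n = as.integer(t(counts)),
    stringsAsFactors = FALSE
  )
  na_tab <- tapply(is.na(ca$category),
                   paste(ca$recipient, ca$timepoint, sep = "\r"), sum)
  attr(res, "na_counts") <- data.frame(
    recipient = key$recipient, timepoint = key$timepoint,
    n_na = as.integer(na_tab[ids]), stringsAsFactors = FALSE)
  res
}

#' Family-level category distribution
#'
#' Counts, per microbial family and ecological category, the number of
#' distinct species ever assigned to that category at any recipient or
#' timepoint. Species not covered by the taxonomy are bucketed as
#' "unclassified".
#'
#' @param ca category assignment table from [categorize_study()].
#' @param taxonomy named character vector species -> family (may be empty).
#' @return data.frame family x category counts (long format: `family`,
#'   `category`, `n_species`).
#' @export
family_category_distribution <- function(ca, taxonomy = character()) {
  lev <- category_levels()
  cc <- ca[!is.na(ca$category), c("species", "category")]
  cc <- unique(cc)
  fam <- taxonomy[cc$species]
  fam[is.na(fam)] <- "unclassified"
  tab <- table(factor(fam), factor(cc$category, levels = lev))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("family", "category", "n_species")
  df[order(df$family, match(df$category, lev)), , drop = FALSE]
}

#' Write a category assignment table as TSV
#' @param ca assignment table from [categorize_study()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(ca, path) {
  utils::write.table(ca, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
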