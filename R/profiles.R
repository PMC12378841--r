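#' Construct a taxonomic profile matrix
#'
#' A `profile_matrix` is the basic abundance container: a numeric matrix of
#' taxa (rows) by samples (columns), holding either read counts or relative
#' abundances (proportions). It is the input to presence calling, donor
#' core-set extraction and all abundance analyses.
#'
#' @param values numeric matrix, taxa x samples, non-negative.
#' @param taxa_ids character vector of unique species (mOTU-style) identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   `colnames(values)`.
#' @param is_relative logical; `TRUE` if columns are proportions summing to 1.
#' @return An object of class `profile_matrix`: the numeric matrix with
#'   dimnames set and attributes `is_relative` and `empty_samples` (ids of
#'   all-zero sample columns).
#' @export
profile_matrix <- function(values, taxa_ids = rownames(values),
                           sample_ids = colnames(values), is_relative = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("profile values must be numeric")
  storage.mode(values) <- "double"
  if (is.null(taxa_ids) || is.null(sample_ids))
    stop("taxa_ids and sample_ids are required (or set as dimnames)")
  taxa_ids <- as.character(taxa_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxa_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames do not match matrix dimensions")
  if (anyDuplicated(taxa_ids)) stop("duplicate taxa ids: ",
    paste(unique(taxa_ids[duplicated(taxa_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("profile contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 taxa_ids[neg[1, 1]], sample_ids[neg[1, 2]]))
  dimnames(values) <- list(taxa_ids, sample_ids)
  csum <- colSums(values)
  empty <- sample_ids[csum == 0]
  if (is_relative) {
    bad <- sample_ids[csum > 0 & abs(csum - 1) > 1e-9]
    if (length(bad) > 0)
      stop("declared relative but columns do not sum to 1: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(values, class = c("profile_matrix", "matrix", "array"),
            is_relative = is_relative, empty_samples = empty)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (attr(x, "is_relative")) "relative abundances" else "counts"))
  es <- attr(x, "empty_samples")
  if (length(es) > 0)
    cat("  empty samples: ", paste(es, collapse = ", "), "\n", sep = "")
  invisible(x)
}

is_relative <- function(pm) isTRUE(attr(pm, "is_relative"))

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a taxonomic profile table
#'
#' Reads a mOTUs-style merged profile: TSV with a header row of sample ids and
#' a first column of taxon ids. Gzip-compressed files are read transparently.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @param orientation `"taxa_rows"` (default; taxa x samples) or
#'   `"samples_rows"` for the transposed layout.
#' @param is_relative logical; declare the values as proportions.
#' @return A [profile_matrix].
#' @export
read_profile_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                               is_relative = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("profile file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2) stop("profile table needs an id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(num)[j], v[bad[1]]))
      num[[j]] <- conv
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxa rows: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  profile_matrix(m, is_relative = is_relative)
}

#' Write a profile matrix as TSV
#'
#' Inverse of [read_profile_table()]; values are written as decimal text with
#' up to 12 significant digits, so a write/read round trip reproduces them.
#'
#' @param pm a [profile_matrix].
#' @param path output path (`.gz` to compress).
#' @param id_column name of the taxon id column in the header.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(pm, path, id_column = "motu_id") {
  df <- data.frame(id = rownames(pm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_column
  vals <- as.data.frame(format(unclass(pm), digits = 12, trim = TRUE,
                               scientific = NA))
  df <- cbind(df, vals)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a profile to relative abundances
#'
#' Each nonempty sample column is rescaled to sum to 1. All-zero columns are
#' kept (and flagged in the `empty_samples` attribute) rather than dropped, so
#' that missingness remains explicit downstream. Idempotent on already-relative
#' input.
#'
#' @param pm a [profile_matrix].
#' @return A relative [profile_matrix].
#' @export
to_relative_abundance <- function(pm) {
  if (ncol(pm) < 1) stop("profile has no samples")
  m <- unclass(pm)
  attr(m, "is_relative") <- NULL
  attr(m, "empty_samples") <- NULL
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  profile_matrix(m, is_relative = TRUE)
}

#' Default visit schedule
#'
#' The nine scheduled stool-sampling visits, expressed in weeks since the first
#' FMT: a baseline sample before pretreatment, a pre-FMT sample after
#' pretreatment, one sample after each of the four weekly FMTs, and follow-up
#' samples corresponding to study weeks 8, 10 and 14.
#'
#' @return data.frame with columns `timepoint` (ordered labels) and `week`.
#' @export
default_schedule <- function() {
  data.frame(
    timepoint = c("baseline", "pre_fmt", "post_1", "post_2", "post_3",
                  "post_4", "week_8", "week_10", "week_14"),
    week = c(-3, 0, 1, 2, 3, 4, 5, 7, 11),
    stringsAsFactors = FALSE
  )
}

#' Read a visit schedule from YAML
#'
#' @param path YAML file mapping timepoint labels to week values (weeks since
#'   first FMT).
#' @return data.frame `timepoint`, `week`, ordered by week.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y) && !is.null(y$schedule)) y <- y$schedule
  wk <- vapply(y, as.numeric, numeric(1))
  sch <- data.frame(timepoint = names(wk), week = unname(wk),
                    stringsAsFactors = FALSE)
  sch[order(sch$week), , drop = FALSE]
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("timepoint", "week") %in% names(schedule)))
  if (anyDuplicated(schedule$timepoint)) stop("duplicate timepoint labels")
  if (is.unsorted(schedule$week, strictly = TRUE))
    stop("schedule weeks must be strictly increasing")
  schedule
}

#' Construct a study design
#'
#' Binds together the subject table (donors and recipients with donor
#' assignment, response status and covariates), the visit schedule, and the
#' sample map linking each sequenced sample to a subject and (for recipients)
#' a scheduled timepoint.
#'
#' @param subjects data.frame with columns `subject_id`, `role` ("donor" or
#'   "recipient"), `donor_id` (recipients), `response` ("responder",
#'   "non_responder" or "unknown"), `sex`, `pretreatment`, `age`.
#' @param sample_map data.frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (NA allowed for donor samples).
#' @param schedule data.frame `timepoint`, `week`; see [default_schedule()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(subjects, sample_map, schedule = default_schedule()) {
  schedule <- validate_schedule(schedule)
  req <- c("subject_id", "role")
  if (!all(req %in% names(subjects))) stop("subjects needs subject_id, role")
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  if (!all(subjects$role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient'")
  for (col in c("donor_id", "response", "sex", "pretreatment"))
    if (is.null(subjects[[col]])) subjects[[col]] <- NA_character_
  if (is.null(subjects[["age"]])) subjects[["age"]] <- NA_real_
  rec <- subjects[subjects$role == "recipient", ]
  donors <- subjects$subject_id[subjects$role == "donor"]
  bad <- rec$subject_id[is.na(rec$donor_id) | !(rec$donor_id %in% donors)]
  if (length(bad) > 0)
    stop("recipients without a valid donor assignment: ",
         paste(bad, collapse = ", "))
  sample_map$sample_id <- as.character(sample_map$sample_id)
  sample_map$subject_id <- as.character(sample_map$subject_id)
  if (anyDuplicated(sample_map$sample_id)) stop("duplicate sample ids")
  if (!all(sample_map$subject_id %in% subjects$subject_id))
    stop("sample map references unknown subjects: ",
         paste(setdiff(sample_map$subject_id, subjects$subject_id), collapse = ", "))
  rmap <- sample_map[sample_map$subject_id %in% rec$subject_id, ]
  if (any(is.na(rmap$timepoint)))
    stop("recipient samples must carry a timepoint label")
  unk <- setdiff(rmap$timepoint, schedule$timepoint)
  if (length(unk) > 0)
    stop("unknown timepoint labels: ", paste(unk, collapse = ", "))
  key <- paste(rmap$subject_id, rmap$timepoint)
  if (anyDuplicated(key))
    stop("duplicate recipient (subject, timepoint) samples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(subjects = subjects, sample_map = sample_map,
                 schedule = schedule),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  nrec <- sum(x$subjects$role == "recipient")
  ndon <- sum(x$subjects$role == "donor")
  cat(sprintf("study_design: %d recipients, %d donors, %d samples, %d timepoints\n",
              nrec, ndon, nrow(x$sample_map), nrow(x$schedule)))
  invisible(x)
}

#' Read study metadata from CSV
#'
#' @param path CSV with columns `sample_id`, `subject_id`, `role`, `donor_id`,
#'   `timepoint`, `response`, `sex`, `pretreatment`, `age` (one row per
#'   sample; subject-level fields repeated).
#' @param schedule visit schedule; see [default_schedule()] and
#'   [read_schedule()].
#' @return A [study_design].
#' @export
read_metadata <- function(path, schedule = default_schedule()) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "role", "donor_id", "timepoint",
           "response", "sex", "pretreatment", "age")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  df$timepoint[df$timepoint == ""] <- NA_character_
  df$donor_id[df$donor_id == ""] <- NA_character_
  subjects <- unique(df[, c("subject_id", "role", "donor_id", "response",
                            "sex", "pretreatment", "age")])
  if (anyDuplicated(subjects$subject_id))
    stop("inconsistent subject-level metadata across samples of: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  study_design(subjects, df[, c("sample_id", "subject_id", "timepoint")],
               schedule)
}

#' Recipients of a study design
#' @param design a [study_design].
#' @return character vector of recipient subject ids.
#' @export
recipients <- function(design) {
  design$subjects$subject_id[design$subjects$role == "recipient"]
}

#' Sample lookup for one recipient
#' @noRd
recipient_samples <- function(design, recipient_id) {
  sm <- design$sample_map
  sm <- sm[sm$subject_id == recipient_id & !is.na(sm$timepoint), ]
  stats::setNames(sm$sample_id, sm$timepoint)
}

#' Call presence/absence per recipient, species and timepoint
#'
#' Converts abundances to a three-state presence dataset. A species is
#' `present` (1) at a visit when its abundance exceeds `detect_min` in that
#' sample, `absent` (0) when the sample exists but the abundance does not
#' exceed the threshold, and `missing` (NA) when no sample was collected at
#' that visit. The default `detect_min = 0` treats any nonzero read support as
#' presence; donor-side filtering is handled separately by the core-microbiota
#' threshold.
#'
#' @param pm a [profile_matrix] (counts or relative; relative abundances are
#'   computed internally when `detect_min > 0`).
#' @param design a [study_design].
#' @param detect_min presence threshold on relative abundance (strict `>`).
#' @return A 3-d integer array of class `presence_matrix`, dimensions
#'   species x timepoint x recipient, values 1/0/NA, with the schedule stored
#'   in the `schedule` attribute.
#' @export
call_presence <- function(pm, design, detect_min = 0) {
  stopifnot(inherits(pm, "profile_matrix"), inherits(design, "study_design"))
  if (detect_min > 0 && !is_relative(pm)) pm <- to_relative_abundance(pm)
  recs <- recipients(design)
  tps <- design$schedule$timepoint
  needed <- design$sample_map$sample_id[
    design$sample_map$subject_id %in% recs & !is.na(design$sample_map$timepoint)]
  absent <- setdiff(needed, colnames(pm))
  if (length(absent) > 0)
    stop("samples in design absent from profile: ",
         paste(absent, collapse = ", "))
  arr <- array(NA_integer_,
               dim = c(nrow(pm), length(tps), length(recs)),
               dimnames = list(rownames(pm), tps, recs))
  for (r in recs) {
    smp <- recipient_samples(design, r)
    for (tp in names(smp)) {
      arr[, tp, r] <- as.integer(pm[, smp[[tp]]] > detect_min)
    }
  }
  structure(arr, class = c("presence_matrix", "array"),
            schedule = design$schedule, detect_min = detect_min)
}

#' @export
print.presence_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("presence_matrix: %d species x %d timepoints x %d recipients\n",
              d[1], d[2], d[3]))
  cat(sprintf("  missing slots: %d of %d (recipient x timepoint)\n",
              sum(is.na(x[1, , ])), d[2] * d[3]))
  invisible(x)
}
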