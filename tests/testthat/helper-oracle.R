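# Independent brute-force evaluator of the categorisation rules. Written
# declaratively (per-timepoint recomputation from the rule definitions, no
# mutable state machine) so it can serve as an oracle for categorize_series().

oracle_labels <- function(origin) {
  switch(origin,
    recipient = c("Resident", "Recipient transient", "Species loss"),
    donor     = c("Colonisation", "Donor transient", "Rejection"),
    novel     = c("Novel", "Novel transient", "Novel loss"))
}

oracle_categorize <- function(origin, st, variant) {
  labs <- oracle_labels(origin)
  n <- length(st)
  out <- rep(NA_character_, n)
  obs <- which(!is.na(st))
  if (length(obs) == 0) return(out)
  # detection: recipient species are detected from the series start;
  # donor/novel species from their first observed presence
  d <- if (origin == "recipient") obs[1] else {
    p <- obs[st[obs] == 1]
    if (length(p) == 0) return(out)
    p[1]
  }
  post <- obs[obs >= d]
  absences <- post[st[post] == 0]
  allow <- variant %in% c("base", "s2", "s3")
  tol <- if (allow && length(absences) > 0) absences[1] else 0L
  counted <- setdiff(absences, tol)
  for (t in post) {
    if (st[t] == 0) {
      out[t] <- if (t == tol) NA_character_ else labs[3]
    } else {
      stable <- switch(variant,
        base = ,
        s1 = length(counted[counted < t]) == 0,
        s2 = if (t == d || t == obs[1]) TRUE else {
          prev <- max(obs[obs < t])
          st[prev] == 1
        },
        s3 = ,
        s4 = length(counted) == 0)
      out[t] <- if (stable) labs[1] else labs[2]
    }
  }
  out
}

# enumerate all presence/absence patterns of a given length
all_patterns <- function(len) {
  g <- expand.grid(rep(list(c(0L, 1L)), len))
  as.matrix(g)
}
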