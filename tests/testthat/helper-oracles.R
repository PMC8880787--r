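# Independent brute-force oracles used by the property suites. Each is a
# deliberately naive second implementation, kept apart from the package's
# code paths.

# Leftmost-longest tiling oracle: enumerate every (position, entry) match by
# direct field comparison, then greedily take, at each position in order,
# the longest available match and discard everything it overlaps.
oracle_leftmost_longest <- function(tokens, entries) {
  T_ <- nrow(tokens)
  matches <- list()
  for (ei in seq_along(entries)) {
    pat <- entries[[ei]]$pattern
    L <- length(pat)
    if (L > T_) next
    for (t in seq_len(T_ - L + 1)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        con <- pat[[j]]
        for (f in names(con)) {
          if (tokens[[f]][t + j - 1] != con[[f]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) matches[[length(matches) + 1]] <- c(start = t - 1L, len = L)
    }
  }
  if (length(matches) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, matches)
  m <- m[order(m[, "start"], -m[, "len"]), , drop = FALSE]
  out <- list()
  pos <- 0L
  repeat {
    avail <- m[m[, "start"] >= pos, , drop = FALSE]
    if (nrow(avail) == 0) break
    first <- min(avail[, "start"])
    cand <- avail[avail[, "start"] == first, , drop = FALSE]
    pick <- cand[which.max(cand[, "len"]), ]
    out[[length(out) + 1]] <- data.frame(start = pick[["start"]],
                                         end = pick[["start"]] + pick[["len"]])
    pos <- pick[["start"]] + pick[["len"]]
  }
  do.call(rbind, out)
}

# Set-intersection scoring oracle over (doc, sentence, tag, start, end) keys.
oracle_score <- function(gold, pred) {
  key <- function(s) {
    if (nrow(s) == 0) return(character())
    unique(paste(if ("doc_id" %in% names(s)) s$doc_id else "",
                 s$sentence_id, s$tag_id, s$start, s$end))
  }
  g <- key(gold); p <- key(pred); c <- length(intersect(g, p))
  prec <- if (length(p) > 0) c / length(p) else 0
  rec <- if (length(g) > 0) c / length(g) else 0
  list(precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# random valid span set: per channel, non-overlapping spans over T tokens
random_span_set <- function(T_, channels) {
  out <- list()
  for (ch in channels) {
    t <- 0L
    while (t < T_) {
      if (runif(1) < 0.4) {
        len <- sample.int(min(3L, T_ - t), 1)
        out[[length(out) + 1]] <- data.frame(
          doc_id = "", sentence_id = 1L, tag_id = ch,
          start = t, end = t + len, source = "manual", verified = TRUE,
          stringsAsFactors = FALSE)
        t <- t + len
      } else {
        t <- t + 1L
      }
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    data.frame(doc_id = character(), sentence_id = integer(),
               tag_id = character(), start = integer(), end = integer(),
               source = character(), verified = logical(),
               stringsAsFactors = FALSE)
}
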