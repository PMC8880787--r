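# Trainable sequence labeler: morpheme sequence -> C x T IOB2 matrix.
#
# The shipped model is a per-channel averaged margin perceptron over a
# +/-1-token window of surface forms plus the current lemma and POS; each
# channel is an independent 3-way {O,B,I} token classifier whose output is
# repaired into valid IOB2 by decode_matrix(). The window features stand in
# for the bidirectional context a recurrent encoder would provide; no
# deep-learning backend is available in the supported dependency set, so
# this dependency-light learner is the default (and only) backend. Config
# fields mirror the reference training protocol; embed_dim/hidden_dim and
# optimizer are retained for interface fidelity but are inert here.

#' Labeler configuration
#'
#' Defaults mirror the reference training protocol: 50 epochs, batch size
#' 32 (sentences per update), learning rate 0.001. `embed_dim`,
#' `hidden_dim` and `optimizer` are accepted for interface compatibility
#' and are inert for the perceptron backend.
#'
#' @param epochs,batch_size Positive integers.
#' @param learning_rate Positive step size.
#' @param embed_dim,hidden_dim Positive integers (inert).
#' @param seed Integer seed driving batch order.
#' @param optimizer Only `"adam"` is accepted (inert).
#' @return A `labeler_config` list.
#' @export
labeler_config <- function(epochs = 50L, batch_size = 32L,
                           learning_rate = 0.001, embed_dim = 300L,
                           hidden_dim = 300L, seed = 1L,
                           optimizer = "adam") {
  if (epochs < 1 || batch_size < 1 || embed_dim < 1 || hidden_dim < 1) {
    stop_input("epochs, batch_size, embed_dim, hidden_dim must be positive")
  }
  if (learning_rate <= 0) stop_input("learning_rate must be > 0")
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 seed = as.integer(seed), optimizer = optimizer),
            class = "labeler_config")
}

#' Split a corpus into train/development/test sets
#'
#' Document-level partition (whole documents, so no subject's sentences
#' leak across sets). Sizes follow the ratio with each size floored and the
#' remainder assigned train-first; the shuffle is deterministic in `seed`.
#'
#' @param corpus A non-empty `pragma_corpus`.
#' @param ratios Three non-negative weights, default `c(8, 1, 1)`.
#' @param seed Integer seed.
#' @return List of three corpora: `train`, `dev`, `test` (spans, when
#'   present, travel with their documents).
#' @export
split_corpus <- function(corpus, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  n <- length(corpus$documents)
  if (n == 0) stop_input("cannot split an empty corpus")
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) <= 0) {
    stop_input("ratios must be three non-negative weights with positive sum")
  }
  sizes <- floor(n * ratios / sum(ratios))
  i <- 1L
  while (sum(sizes) < n) {       # remainder goes train-first
    sizes[i] <- sizes[i] + 1L
    i <- if (i == 3L) 1L else i + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  cuts <- cumsum(sizes)
  list(train = corpus_subset(corpus, perm[seq_len(cuts[1])]),
       dev = corpus_subset(corpus, perm[seq_len(cuts[2])[-seq_len(cuts[1])]]),
       test = corpus_subset(corpus, perm[setdiff(seq_len(n), seq_len(cuts[2]))]))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- feature extraction ----

build_vocab <- function(docs) {
  surf <- unique(unlist(lapply(docs, function(d) d$tokens$surface)))
  lem <- unique(unlist(lapply(docs, function(d) d$tokens$lemma)))
  pos <- unique(unlist(lapply(docs, function(d) d$tokens$pos)))
  list(surface = sort(surf), lemma = sort(lem), pos = sort(pos))
}

# Sparse token-by-feature design matrix for a list of documents, plus the
# token -> (doc, sentence) bookkeeping needed to reassemble matrices.
featurize <- function(docs, vocab) {
  Vs <- length(vocab$surface); Vl <- length(vocab$lemma); Vp <- length(vocab$pos)
  # per-slot block sizes; surface slots reserve UNK/BOS/EOS ids
  bs <- Vs + 3L
  blocks <- c(prev = bs, cur = bs, nxt = bs, lemma = Vl + 1L, pos = Vp + 1L,
              bias = 1L)
  offs <- cumsum(c(0L, blocks))[seq_along(blocks)]
  names(offs) <- names(blocks)
  F_ <- sum(blocks)
  UNK <- Vs + 1L; BOS <- Vs + 2L; EOS <- Vs + 3L

  sent_doc <- character(); sent_sid <- integer(); sent_len <- integer()
  ii <- list(); jj <- list()
  nrow_total <- 0L
  for (d in docs) {
    tok <- d$tokens
    for (sid in unique(tok$sentence_id)) {
      s <- tok[tok$sentence_id == sid, ]
      T_ <- nrow(s)
      sidx <- match(s$surface, vocab$surface); sidx[is.na(sidx)] <- UNK
      lidx <- match(s$lemma, vocab$lemma); lidx[is.na(lidx)] <- Vl + 1L
      pidx <- match(s$pos, vocab$pos); pidx[is.na(pidx)] <- Vp + 1L
      prev <- c(BOS, sidx[-T_])
      nxt <- c(sidx[-1], EOS)
      rows <- nrow_total + seq_len(T_)
      ii[[length(ii) + 1]] <- rep(rows, 6L)
      jj[[length(jj) + 1]] <- c(offs["prev"] + prev, offs["cur"] + sidx,
                                offs["nxt"] + nxt, offs["lemma"] + lidx,
                                offs["pos"] + pidx, rep(offs["bias"] + 1L, T_))
      nrow_total <- nrow_total + T_
      sent_doc <- c(sent_doc, d$doc_id)
      sent_sid <- c(sent_sid, sid)
      sent_len <- c(sent_len, T_)
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(nrow_total, F_))
  list(X = X, sent_doc = sent_doc, sent_sid = sent_sid, sent_len = sent_len,
       n_features = F_)
}

# token labels (1=O, 2=B, 3=I) per channel for a featurized corpus
gold_labels <- function(corpus, feats, channels) {
  N <- sum(feats$sent_len)
  Y <- matrix(1L, nrow = N, ncol = length(channels))
  spans <- corpus$spans
  if (is.null(spans)) spans <- empty_spans()
  off <- cumsum(c(0L, feats$sent_len))
  key <- paste(feats$sent_doc, feats$sent_sid)
  for (i in seq_len(nrow(spans))) {
    si <- match(paste(spans$doc_id[i], spans$sentence_id[i]), key)
    ci <- match(spans$tag_id[i], channels)
    if (is.na(si) || is.na(ci)) next
    rows <- off[si] + (spans$start[i] + 1L):spans$end[i]
    Y[rows[1], ci] <- 2L
    if (length(rows) > 1) Y[rows[-1], ci] <- 3L
  }
  Y
}

#' Train the sequence labeler
#'
#' Per-channel averaged margin perceptron (see the package vignette for the
#' model account). Training order is seeded and fully deterministic; the
#' per-epoch log records the summed margin loss and, when a development set
#' is given, span-level micro F1, and the checkpoint with the best dev F1
#' is the one returned.
#'
#' @param train Annotated `pragma_corpus` (gold spans in `$spans`).
#' @param dev Optional annotated `pragma_corpus` used for model selection.
#' @param channels Ordered tag ids to model; defaults to the tags present in
#'   the training spans. A channel with no gold span anywhere triggers a
#'   warning but is retained.
#' @param config A [labeler_config()].
#' @return A `trained_labeler`: weights, vocabulary, channels, config,
#'   `training_log` (epoch, loss, dev_f1), `best_epoch`.
#' @export
train_labeler <- function(train, dev = NULL, channels = NULL,
                          config = labeler_config()) {
  stopifnot(inherits(train, "pragma_corpus"))
  if (length(train$documents) == 0) stop_input("empty training set")
  if (is.null(train$spans)) stop_input("training corpus carries no gold spans")
  if (is.null(channels)) channels <- sort(unique(train$spans$tag_id))
  if (length(channels) == 0) stop_input("no channels to train on")
  absent <- setdiff(channels, unique(train$spans$tag_id))
  if (length(absent) > 0) {
    pm_warn(sprintf("channel(s) with no gold spans in training data: %s",
                    paste(absent, collapse = ", ")))
  }

  vocab <- build_vocab(train$documents)
  feats <- featurize(train$documents, vocab)
  Y <- gold_labels(train, feats, channels)
  C <- length(channels)
  F_ <- feats$n_features
  lr <- config$learning_rate

  W <- lapply(seq_len(C), function(i) Matrix::Matrix(0, F_, 3, sparse = TRUE))
  Wsum <- lapply(seq_len(C), function(i) Matrix::Matrix(0, F_, 3, sparse = TRUE))

  n_sent <- length(feats$sent_len)
  off <- cumsum(c(0L, feats$sent_len))
  batch_of <- function(sids) unlist(lapply(sids, function(s) (off[s] + 1L):off[s + 1L]))

  log_epoch <- integer(); log_loss <- numeric(); log_dev <- numeric()
  best_f1 <- -Inf; best_W <- NULL; best_epoch <- NA_integer_

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + ep, sample.int(n_sent))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      rows <- batch_of(b)
      Xb <- feats$X[rows, , drop = FALSE]
      for (ci in seq_len(C)) {
        S <- as.matrix(Xb %*% W[[ci]])
        yb <- Y[rows, ci]
        true_s <- S[cbind(seq_along(yb), yb)]
        S[cbind(seq_along(yb), yb)] <- -Inf
        rival <- max.col(S, ties.method = "first")
        rival_s <- S[cbind(seq_along(yb), rival)]
        margin <- pmax(0, 1 + rival_s - true_s)
        ep_loss <- ep_loss + sum(margin)
        viol <- which(margin > 0)
        if (length(viol) > 0) {
          D <- Matrix::sparseMatrix(
            i = c(viol, viol), j = c(yb[viol], rival[viol]),
            x = c(rep(lr, length(viol)), rep(-lr, length(viol))),
            dims = c(length(yb), 3))
          W[[ci]] <- W[[ci]] + Matrix::crossprod(Xb, D)
        }
      }
    }
    for (ci in seq_len(C)) Wsum[[ci]] <- Wsum[[ci]] + W[[ci]]
    Wavg <- lapply(Wsum, function(m) m / ep)
    dev_f1 <- NA_real_
    if (!is.null(dev) && length(dev$documents) > 0 && !is.null(dev$spans)) {
      model_ep <- new_trained_labeler(Wavg, vocab, channels, config, NULL, ep)
      pred <- predict_corpus(model_ep, dev)
      dev_f1 <- score_spans(dev$spans, pred)$aggregate$f1
      # ties go to the later (more trained) checkpoint
      if (dev_f1 >= best_f1) { best_f1 <- dev_f1; best_W <- Wavg; best_epoch <- ep }
    } else {
      best_W <- Wavg; best_epoch <- ep
    }
    log_epoch <- c(log_epoch, ep); log_loss <- c(log_loss, ep_loss)
    log_dev <- c(log_dev, dev_f1)
  }

  new_trained_labeler(best_W, vocab, channels, config,
                      data.frame(epoch = log_epoch, loss = log_loss,
                                 dev_f1 = log_dev), best_epoch)
}

new_trained_labeler <- function(weights, vocab, channels, config,
                                training_log, best_epoch) {
  structure(list(weights = weights, vocab = vocab, channels = channels,
                 config = config, training_log = training_log,
                 best_epoch = best_epoch),
            class = "trained_labeler")
}

#' @export
print.trained_labeler <- function(x, ...) {
  cat(sprintf("<trained_labeler> %d channels, %d features, best epoch %s\n",
              length(x$channels), nrow(x$weights[[1]]), x$best_epoch))
  invisible(x)
}

#' Predict label matrices and spans for a document
#'
#' Raw per-channel argmax output is repaired into valid IOB2 (orphan I
#' promoted to B) by [decode_matrix()]; the repair count is reported.
#'
#' @param model A `trained_labeler`.
#' @param doc A `pragma_document`.
#' @return List: `matrices` (one repaired C x T label matrix per sentence,
#'   named by sentence id), `spans` (data frame, `source = "model"`),
#'   `n_repairs`.
#' @export
predict_labeler <- function(model, doc) {
  stopifnot(inherits(model, "trained_labeler"),
            inherits(doc, "pragma_document"))
  if (nrow(doc$tokens) == 0) {
    return(list(matrices = list(), spans = empty_spans(), n_repairs = 0L))
  }
  feats <- featurize(list(doc), model$vocab)
  C <- length(model$channels)
  scores <- lapply(seq_len(C), function(ci)
    as.matrix(feats$X %*% model$weights[[ci]]))
  off <- cumsum(c(0L, feats$sent_len))
  matrices <- list()
  spans <- list()
  n_rep <- 0L
  labs <- c("O", "B", "I")
  for (si in seq_along(feats$sent_len)) {
    rows <- (off[si] + 1L):off[si + 1L]
    m <- matrix("O", nrow = C, ncol = length(rows),
                dimnames = list(model$channels, NULL))
    for (ci in seq_len(C)) {
      m[ci, ] <- labs[max.col(scores[[ci]][rows, , drop = FALSE],
                              ties.method = "first")]
    }
    dec <- decode_matrix(m)
    n_rep <- n_rep + nrow(dec$repairs)
    # store the repaired (valid) matrix
    matrices[[as.character(feats$sent_sid[si])]] <-
      encode_spans(dec$spans, length(rows), model$channels)
    if (nrow(dec$spans) > 0) {
      dec$spans$doc_id <- doc$doc_id
      dec$spans$sentence_id <- feats$sent_sid[si]
      dec$spans$source <- "model"
      dec$spans$verified <- FALSE
      spans[[length(spans) + 1]] <- dec$spans
    }
  }
  spans <- if (length(spans) > 0) as_spans(do.call(rbind, spans)) else empty_spans()
  list(matrices = matrices, spans = sort_spans(spans), n_repairs = n_rep)
}

#' Predict spans for every document of a corpus
#'
#' @param model A `trained_labeler`.
#' @param corpus A `pragma_corpus`.
#' @return Span data frame (`source = "model"`), with the total repair count
#'   in attribute `"n_repairs"`.
#' @export
predict_corpus <- function(model, corpus) {
  stopifnot(inherits(corpus, "pragma_corpus"))
  out <- lapply(corpus$documents, function(d) predict_labeler(model, d))
  spans <- do.call(rbind, c(list(empty_spans()), lapply(out, `[[`, "spans")))
  structure(sort_spans(spans),
            n_repairs = sum(vapply(out, `[[`, integer(1), "n_repairs")))
}

#' Save / load a trained labeler
#'
#' The model artifact is a directory of plain-text files: `config.json`,
#' `channels.txt`, `vocab_*.txt`, `training_log.csv`, and one
#' `weights_<i>.tsv` per channel.
#'
#' @param model A `trained_labeler`.
#' @param dir Directory path (created if needed).
#' @return `save_labeler()`: `dir` invisibly; `load_labeler()`: the model.
#' @export
save_labeler <- function(model, dir) {
  stopifnot(inherits(model, "trained_labeler"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$channels, file.path(dir, "channels.txt"))
  for (f in names(model$vocab)) {
    writeLines(model$vocab[[f]], file.path(dir, sprintf("vocab_%s.txt", f)))
  }
  if (!is.null(model$training_log)) {
    write.table(model$training_log, file.path(dir, "training_log.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  for (ci in seq_along(model$weights)) {
    w <- as.matrix(model$weights[[ci]])
    write.table(w, file.path(dir, sprintf("weights_%03d.tsv", ci)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  writeLines(as.character(model$best_epoch), file.path(dir, "best_epoch.txt"))
  invisible(dir)
}

#' @rdname save_labeler
#' @export
load_labeler <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- labeler_config(cfg$epochs, cfg$batch_size, cfg$learning_rate,
                           cfg$embed_dim, cfg$hidden_dim, cfg$seed,
                           cfg$optimizer)
  channels <- readLines(file.path(dir, "channels.txt"))
  vocab <- lapply(setNames(c("surface", "lemma", "pos"),
                           c("surface", "lemma", "pos")), function(f) {
    p <- file.path(dir, sprintf("vocab_%s.txt", f))
    if (file.exists(p)) readLines(p, encoding = "UTF-8") else character()
  })
  weights <- lapply(seq_along(channels), function(ci) {
    m <- as.matrix(read.delim(file.path(dir, sprintf("weights_%03d.tsv", ci)),
                              header = FALSE))
    dimnames(m) <- NULL
    Matrix::Matrix(m, sparse = TRUE)
  })
  log_path <- file.path(dir, "training_log.csv")
  training_log <- if (file.exists(log_path)) read.delim(log_path, sep = ",") else NULL
  best_epoch <- as.integer(readLines(file.path(dir, "best_epoch.txt"))[1])
  new_trained_labeler(weights, vocab, channels, config, training_log,
                      best_epoch)
}
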