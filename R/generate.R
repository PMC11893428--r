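# Germline-conditioned sampling with a per-layer key/value cache.
# A whole batch of sequences is decoded in lockstep: each step performs a
# handful of (B x d) matrix products and one cached-attention read per head,
# so sampling cost is linear in the generated length.

.sample_batch <- function(model, tag_id, B, temperature, max_len) {
  spec <- model$spec
  d <- spec$d_model
  nh <- spec$n_heads
  hd <- d %/% nh
  half <- hd %/% 2L
  sc <- spec$scaling
  V <- length(model$vocab)
  Tcap <- max_len + 3L  # tag + bos + residues + eos
  rope <- .rope_tables(Tcap, hd, spec$rope_base)
  # per-layer K/V caches, d x (B*Tcap), one column per cached vector,
  # sequence-major; written in place by the C kernel
  Kc <- lapply(seq_len(spec$n_layers), function(l) matrix(0, d, B * Tcap))
  Vc <- lapply(seq_len(spec$n_layers), function(l) matrix(0, d, B * Tcap))
  toks <- matrix(model$tok2id["<pad>"], B, Tcap)
  toks[, 1] <- tag_id
  toks[, 2] <- model$tok2id["<bos>"]
  eos <- model$tok2id["<eos>"]
  finished <- rep(FALSE, B)
  head_cols <- lapply(seq_len(nh), function(hh) ((hh - 1L) * hd + 1L):(hh * hd))
  co_all <- lapply(seq_len(Tcap), function(p) {
    matrix(rope$cos[p, ], B, half, byrow = TRUE)
  })
  si_all <- lapply(seq_len(Tcap), function(p) {
    matrix(rope$sin[p, ], B, half, byrow = TRUE)
  })

  for (pos in seq_len(Tcap - 1L)) {
    co <- co_all[[pos]]
    si <- si_all[[pos]]
    h <- model$base$E[toks[, pos], , drop = FALSE]
    for (l in seq_len(spec$n_layers)) {
      W <- model$base$layers[[l]]
      ad <- model$adapters[[l]]
      a <- .rmsnorm(h)$y
      q <- .lin(a, W$wq, ad$wq, sc)
      k <- .lin(a, W$wk, ad$wk, sc)
      v <- .lin(a, W$wv, ad$wv, sc)
      for (hh in seq_len(nh)) {
        ch <- head_cols[[hh]]
        q[, ch] <- .rope_apply(q[, ch, drop = FALSE], co, si)
        k[, ch] <- .rope_apply(k[, ch, drop = FALSE], co, si)
      }
      .cache_write(Kc[[l]], t(k), pos, Tcap)
      .cache_write(Vc[[l]], t(v), pos, Tcap)
      o <- t(.attn_step(Kc[[l]], Vc[[l]], t(q), pos, nh, Tcap))
      h <- h + .lin(o, W$wo, ad$wo, sc)
      a2 <- .rmsnorm(h)$y
      g <- .lin(a2, W$wgate, ad$wgate, sc)
      u <- .lin(a2, W$wup, ad$wup, sc)
      h <- h + .lin(g * (1 / (1 + exp(-g))) * u, W$wdown, ad$wdown, sc)
    }
    logits <- .rmsnorm(h)$y %*% t(model$base$E)
    gum <- -log(-log(matrix(stats::runif(B * V), B, V)))
    nxt <- max.col(logits / temperature + gum, ties.method = "first")
    nxt[finished] <- model$tok2id["<pad>"]
    toks[, pos + 1L] <- nxt
    finished <- finished | nxt == eos
    if (all(finished)) break
  }

  vapply(seq_len(B), function(b) {
    row <- toks[b, ]
    stop_at <- which(row == eos)
    end <- if (length(stop_at) > 0L) stop_at[1] - 1L else Tcap
    if (end < 3L) return("")
    paste(model$vocab[row[3:end]], collapse = "")
  }, character(1))
}

#' Generate sequences conditioned on a germline
#'
#' Samples autoregressively from the trained model with the germline tag as
#' prefix, at the given temperature, until the end token or `max_len`
#' residues. Samples that fail validation ([validate_sequence()]) or that
#' are unnumberable against the requested germline's reference (identity
#' below the 0.5 numbering floor of [number_sequence()]) are dropped and
#' resampled; duplicates are dropped, so the result contains unique
#' sequences. If the attempt cap is reached first, the partial result is
#' returned with a warning.
#'
#' @param model A trained `nano_generator`.
#' @param germline Conditioning germline (its tag must be in the vocabulary).
#' @param n Number of unique sequences requested.
#' @param temperature Softmax temperature (default 1).
#' @param max_len Maximum residue length (default from the spec).
#' @param seed Integer seed; same seed, model and arguments give an
#'   identical output list.
#' @param refs References used for the numberability filter; defaults to the
#'   bundled references. Set `filter = FALSE` to skip filtering.
#' @param filter Apply the validity/numberability filter (default TRUE).
#' @param attempt_cap Maximum number of raw samples drawn (default `10 * n`).
#' @return A `nano_records` data frame of up to `n` unique sequences labeled
#'   with the requested germline.
#' @export
generate_sequences <- function(model, germline, n, temperature = 1,
                               max_len = NULL, seed = 1L,
                               refs = nano_references(), filter = TRUE,
                               attempt_cap = 10L * n + 100L) {
  stopifnot(inherits(model, "nano_generator"))
  tag <- paste0("<", germline, ">")
  if (!tag %in% model$vocab) stop("unknown germline tag: ", tag)
  if (n == 0L) return(nano_records(character(0), character(0)))
  if (is.null(max_len)) max_len <- model$spec$max_len
  tag_id <- unname(model$tok2id[tag])
  refnames <- vapply(refs, function(r) r$name, character(1))
  ref <- if (filter && germline %in% refnames) {
    refs[[which(refnames == germline)]]
  } else NULL

  seqs <- character(0)
  attempts <- 0L
  withr::with_seed(seed, {
    while (length(seqs) < n && attempts < attempt_cap) {
      B <- min(500L, max(16L, ceiling((n - length(seqs)) * 1.25)))
      B <- min(B, attempt_cap - attempts)
      raw <- .sample_batch(model, tag_id, B, temperature, max_len)
      attempts <- attempts + B
      keep <- vapply(raw, function(s) validate_sequence(s)$ok, logical(1))
      raw <- setdiff(unique(raw[keep]), seqs)
      if (!is.null(ref) && length(raw) > 0L) {
        raw <- raw[.identity_to_ref(raw, ref$seq) >= 0.5]
      }
      seqs <- c(seqs, utils::head(raw, n - length(seqs)))
    }
  })
  if (length(seqs) < n) {
    warning("attempt cap reached: returning ", length(seqs), " of ", n,
            " requested sequences")
  }
  nano_records(sprintf("gen_%s_%04d", gsub("[^A-Za-z0-9]", "", germline),
                       seq_along(seqs)),
               seqs, germline)
}

#' Save / load a generator checkpoint
#'
#' The checkpoint is a single RDS file holding the spec, frozen base and
#' adapter state.
#'
#' @param model A `nano_generator`.
#' @param path Checkpoint file path.
#' @return `save_generator` returns `path` invisibly; `load_generator`
#'   returns the model.
#' @export
save_generator <- function(model, path) {
  stopifnot(inherits(model, "nano_generator"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "nano_generator"))
  model
}
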