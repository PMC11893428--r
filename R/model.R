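# A small decoder-only autoregressive amino-acid language model with LoRA
# adapters, written directly on top of R matrix algebra.
#
# Architecture (per decoder block, pre-norm residual form):
#   h <- h + Wo( attention( rope(Wq a), rope(Wk a), Wv a ) ),  a = rmsnorm(h)
#   h <- h + Wdown( silu(Wgate a2) * (Wup a2) ),               a2 = rmsnorm(h)
# with rotary position embeddings on q/k and a weight-tied output head
# (logits = rmsnorm(h) %*% t(E)). Every base matrix is frozen after
# initialization; the only trainable parameters are the low-rank pairs
# (A, B) attached to the seven projections wq, wk, wv, wo, wgate, wup,
# wdown, which contribute an additive delta:  W x -> W0 x + A (B x).
# B is initialized to zero, so at step 0 the adapted model is
# function-identical to the frozen base.

LORA_TARGETS <- c("wq", "wk", "wv", "wo", "wgate", "wup", "wdown")

#' Specify a LoRA-adapted toy decoder
#'
#' Defaults fix a desk-scale architecture (d_model 128, 4 layers, 4 heads,
#' d_ff 256); the LoRA mechanics, the freeze contract and the
#' germline-conditioning pipeline do not depend on model size. The vocabulary
#' is the 20 amino acids, begin/end/pad tokens, and one conditioning tag per
#' germline.
#'
#' @param germlines Character vector of germline names the model can be
#'   conditioned on (each becomes a tag token).
#' @param d_model,n_layers,n_heads,d_ff Architecture sizes.
#' @param r LoRA rank; must satisfy `r < min(d, k)` over adapted matrices.
#' @param adapted_targets Subset of `wq, wk, wv, wo, wgate, wup, wdown`.
#' @param scaling Multiplier on the low-rank delta (default 1).
#' @param max_len Maximum residue length at sampling time.
#' @param rope_base Rotary embedding base frequency.
#' @return A list of class `lora_spec`.
#' @export
lora_spec <- function(germlines, d_model = 128L, n_layers = 4L, n_heads = 4L,
                      d_ff = 256L, r = 8L, adapted_targets = LORA_TARGETS,
                      scaling = 1, max_len = 160L, rope_base = 10000) {
  stopifnot(length(germlines) >= 1L, d_model %% n_heads == 0L,
            (d_model %/% n_heads) %% 2L == 0L)  # rotary pairs need even head dim
  adapted_targets <- match.arg(adapted_targets, LORA_TARGETS,
                               several.ok = TRUE)
  dims <- .target_dims(d_model, d_ff)
  min_dk <- min(unlist(dims[adapted_targets]))
  if (r >= min_dk) {
    stop("LoRA rank r = ", r, " must be smaller than min(d, k) = ", min_dk,
         " over the adapted matrices")
  }
  vocab <- c(AA20, "<bos>", "<eos>", "<pad>", paste0("<", germlines, ">"))
  structure(list(germlines = germlines, d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 r = as.integer(r), adapted_targets = adapted_targets,
                 scaling = scaling, max_len = as.integer(max_len),
                 rope_base = rope_base, vocab = vocab),
            class = "lora_spec")
}

.target_dims <- function(d, dff) {
  list(wq = c(d, d), wk = c(d, d), wv = c(d, d), wo = c(d, d),
       wgate = c(d, dff), wup = c(d, dff), wdown = c(dff, d))
}

#' Build the frozen base model and attach LoRA adapters
#'
#' Initializes the base weights from `seed`, attaches one `(A, B)` pair per
#' adapted projection per layer with `B = 0` (so the adapted model is
#' exactly function-identical to the base at step 0), and freezes the base:
#' training updates only the adapters.
#'
#' @param spec A `lora_spec`.
#' @param seed Integer seed for base and adapter initialization.
#' @return An object of class `nano_generator`.
#' @export
attach_lora <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lora_spec"))
  d <- spec$d_model
  dff <- spec$d_ff
  V <- length(spec$vocab)
  dims <- .target_dims(d, dff)
  model <- withr::with_seed(seed, {
    base <- list(
      E = matrix(stats::rnorm(V * d, sd = 1 / sqrt(d)), V, d),
      layers = lapply(seq_len(spec$n_layers), function(l) {
        lapply(dims, function(dk) {
          matrix(stats::rnorm(dk[1] * dk[2], sd = 1 / sqrt(dk[1])),
                 dk[1], dk[2])
        })
      }))
    adapters <- lapply(seq_len(spec$n_layers), function(l) {
      out <- lapply(spec$adapted_targets, function(t) {
        dk <- dims[[t]]
        list(A = matrix(stats::rnorm(dk[1] * spec$r, sd = 1 / sqrt(dk[1])),
                        dk[1], spec$r),
             B = matrix(0, spec$r, dk[2]))
      })
      names(out) <- spec$adapted_targets
      out
    })
    list(base = base, adapters = adapters)
  })
  structure(list(spec = spec, base = model$base, adapters = model$adapters,
                 vocab = spec$vocab,
                 tok2id = stats::setNames(seq_along(spec$vocab), spec$vocab),
                 trained = FALSE, training_log = NULL,
                 base_checksum = list(initial = base_checksum_of(model$base))),
            class = "nano_generator")
}

#' @export
print.nano_generator <- function(x, ...) {
  s <- x$spec
  cat("<nano_generator> d_model", s$d_model, "x", s$n_layers, "layers,",
      s$n_heads, "heads, d_ff", s$d_ff, "| LoRA r =", s$r, "on",
      paste(s$adapted_targets, collapse = ","), "\n")
  cat("  vocab:", length(x$vocab), "tokens | trained:", x$trained,
      "| trainable fraction:", sprintf("%.4f", trainable_fraction(x)), "\n")
  invisible(x)
}

#' Digest of the frozen base weights
#'
#' @param base The `$base` component of a `nano_generator`.
#' @return A SHA-256 digest string; bitwise identity of the base weights
#'   before and after training is the freeze contract.
#' @export
base_checksum_of <- function(base) {
  digest::digest(base, algo = "sha256")
}

#' Fraction of parameters that are trainable
#'
#' Ratio of adapter (A, B) parameters to total parameters (frozen base plus
#' adapters). Deterministic from the spec alone: for each adapted `d x k`
#' matrix the adapters add `d*r + r*k` parameters.
#'
#' @param model A `nano_generator`.
#' @return A fraction in \[0, 1); 0 when no adapters are attached.
#' @export
trainable_fraction <- function(model) {
  stopifnot(inherits(model, "nano_generator"))
  n_base <- length(model$base$E) +
    sum(vapply(model$base$layers,
               function(l) sum(vapply(l, length, numeric(1))), numeric(1)))
  n_ad <- if (length(model$adapters) == 0L) 0 else {
    sum(vapply(model$adapters, function(l) {
      sum(vapply(l, function(ab) length(ab$A) + length(ab$B), numeric(1)))
    }, numeric(1)))
  }
  n_ad / (n_base + n_ad)
}

# Tokenize labeled records into id vectors: [tag][bos]residues[eos].
.tokenize_records <- function(model, records) {
  if (any(is.na(records$germline))) {
    stop("unlabeled record(s): ",
         paste(utils::head(records$id[is.na(records$germline)], 3),
               collapse = ", "))
  }
  tags <- paste0("<", records$germline, ">")
  unknown <- setdiff(unique(tags), model$vocab)
  if (length(unknown) > 0L) {
    stop("germline tag(s) not in model vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  lapply(seq_len(nrow(records)), function(i) {
    chars <- strsplit(records$seq[i], "", fixed = TRUE)[[1]]
    unname(c(model$tok2id[tags[i]], model$tok2id["<bos>"],
             model$tok2id[chars], model$tok2id["<eos>"]))
  })
}
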