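# Teacher-forced forward pass, hand-derived backward pass, and the Adam
# training loop that updates only the LoRA adapters.
#
# Batches group sequences of equal token length, so activations for a batch
# of B sequences of n positions are stored as (B*n) x d matrices with rows
# ordered sequence-major (row (b-1)*n + t is position t of sequence b).

.rmsnorm <- function(x, eps = 1e-6) {
  rs <- sqrt(.rowMeans(x * x, nrow(x), ncol(x)) + eps)
  list(y = x / rs, rs = rs)
}

.rmsnorm_bwd <- function(dy, y, rs) {
  (dy - y * .rowMeans(dy * y, nrow(y), ncol(y))) / rs
}

# rotary embedding tables for positions 1..n (0-based phase), half-width hd/2
.rope_tables <- function(n, hd, base) {
  half <- hd / 2
  inv <- base^(-(2 * (seq_len(half) - 1)) / hd)
  ang <- outer(seq_len(n) - 1, inv)   # n x half
  list(cos = cos(ang), sin = sin(ang))
}

# apply rotation to an (m x hd) block given pre-expanded cos/sin matrices
# (m x hd/2); pass -sin to invert the rotation (used in the backward pass)
.rope_apply <- function(x, co, si) {
  half <- ncol(x) / 2
  odd <- seq_len(half) * 2 - 1
  even <- odd + 1
  x1 <- x[, odd, drop = FALSE]
  x2 <- x[, even, drop = FALSE]
  out <- x
  out[, odd] <- x1 * co - x2 * si
  out[, even] <- x1 * si + x2 * co
  out
}

.lin <- function(x, W, ad, scaling) {
  y <- x %*% W
  if (!is.null(ad)) y <- y + (x %*% ad$A) %*% ad$B * scaling
  y
}

# backward of .lin: returns dx and accumulates adapter grads into `grads`
# (an environment keyed like the adapter list)
.lin_bwd <- function(x, dy, W, ad, scaling, grads, layer, target) {
  dx <- tcrossprod(dy, W)
  if (!is.null(ad)) {
    dyB <- tcrossprod(dy, ad$B) * scaling
    dx <- dx + tcrossprod(dyB, ad$A)
    g <- grads$g[[layer]][[target]]
    g$A <- g$A + crossprod(x, dyB)
    g$B <- g$B + crossprod(x %*% ad$A, dy) * scaling
    grads$g[[layer]][[target]] <- g
  }
  dx
}

# Forward pass over a batch; ids is a B x T integer matrix.
# Returns loss and, when backward = TRUE, adapter gradients.
.model_pass <- function(model, ids, backward = TRUE) {
  spec <- model$spec
  d <- spec$d_model
  nh <- spec$n_heads
  hd <- d %/% nh
  sc <- spec$scaling
  B <- nrow(ids)
  T <- ncol(ids)
  n <- T - 1L
  X <- ids[, 1:n, drop = FALSE]
  Y <- ids[, 2:T, drop = FALSE]
  rows_b <- function(b) ((b - 1L) * n + 1L):(b * n)
  pos_idx <- rep(seq_len(n), times = B)

  rope <- .rope_tables(n, hd, spec$rope_base)
  co <- rope$cos[pos_idx, , drop = FALSE]
  si <- rope$sin[pos_idx, , drop = FALSE]
  H <- model$base$E[as.vector(t(X)), , drop = FALSE]
  ad_layers <- model$adapters
  cache <- vector("list", spec$n_layers)
  mask_ut <- which(upper.tri(matrix(0, n, n)))
  seq_n <- seq_len(n)
  inv_sqrt_hd <- 1 / sqrt(hd)

  for (l in seq_len(spec$n_layers)) {
    W <- model$base$layers[[l]]
    ad <- ad_layers[[l]]
    Hin <- H
    nm1 <- .rmsnorm(Hin)
    a <- nm1$y
    Q <- .lin(a, W$wq, ad$wq, sc)
    K <- .lin(a, W$wk, ad$wk, sc)
    Vv <- .lin(a, W$wv, ad$wv, sc)
    O <- matrix(0, B * n, d)
    Ps <- vector("list", B * nh)
    for (h in seq_len(nh)) {
      ch <- ((h - 1L) * hd + 1L):(h * hd)
      Qh <- .rope_apply(Q[, ch, drop = FALSE], co, si)
      Kh <- .rope_apply(K[, ch, drop = FALSE], co, si)
      Q[, ch] <- Qh
      K[, ch] <- Kh
      for (b in seq_len(B)) {
        rb <- rows_b(b)
        S <- tcrossprod(Qh[rb, , drop = FALSE],
                        Kh[rb, , drop = FALSE]) * inv_sqrt_hd
        S[mask_ut] <- -Inf
        S <- exp(S - S[cbind(seq_n, max.col(S, ties.method = "first"))])
        P <- S / .rowSums(S, n, n)
        Ps[[(h - 1L) * B + b]] <- P
        O[rb, ch] <- P %*% Vv[rb, ch, drop = FALSE]
      }
    }
    AO <- .lin(O, W$wo, ad$wo, sc)
    Hmid <- Hin + AO
    nm2 <- .rmsnorm(Hmid)
    a2 <- nm2$y
    G <- .lin(a2, W$wgate, ad$wgate, sc)
    U <- .lin(a2, W$wup, ad$wup, sc)
    sg <- 1 / (1 + exp(-G))
    Z <- G * sg * U
    Ff <- .lin(Z, W$wdown, ad$wdown, sc)
    H <- Hmid + Ff
    cache[[l]] <- list(Hin = Hin, nm1 = nm1, Q = Q, K = K, V = Vv, O = O,
                       Ps = Ps, Hmid = Hmid, nm2 = nm2, G = G, U = U,
                       sg = sg, Z = Z)
  }

  nm3 <- .rmsnorm(H)
  logits <- nm3$y %*% t(model$base$E)
  lmax <- logits[cbind(seq_len(B * n), max.col(logits, ties.method = "first"))]
  Pfull <- exp(logits - lmax)
  Pfull <- Pfull / .rowSums(Pfull, B * n, ncol(Pfull))
  yvec <- as.vector(t(Y))
  idx <- cbind(seq_len(B * n), yvec)
  loss <- -mean(log(pmax(Pfull[idx], 1e-12)))
  if (!is.finite(loss)) stop("non-finite training loss (diverged)")
  if (!backward) return(list(loss = loss, n_tokens = B * n))

  grads <- new.env()
  grads$g <- lapply(ad_layers, function(l) {
    lapply(l, function(ab) list(A = ab$A * 0, B = ab$B * 0))
  })

  dlogits <- Pfull
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / (B * n)
  da3 <- dlogits %*% model$base$E
  dH <- .rmsnorm_bwd(da3, nm3$y, nm3$rs)

  for (l in rev(seq_len(spec$n_layers))) {
    W <- model$base$layers[[l]]
    ad <- ad_layers[[l]]
    cc <- cache[[l]]
    # FFN
    dF <- dH
    dZ <- .lin_bwd(cc$Z, dF, W$wdown, ad$wdown, sc, grads, l, "wdown")
    dS_ <- dZ * cc$U
    dU <- dZ * cc$G * cc$sg
    dG <- dS_ * cc$sg * (1 + cc$G * (1 - cc$sg))
    da2 <- .lin_bwd(cc$nm2$y, dG, W$wgate, ad$wgate, sc, grads, l, "wgate") +
      .lin_bwd(cc$nm2$y, dU, W$wup, ad$wup, sc, grads, l, "wup")
    dHmid <- dH + .rmsnorm_bwd(da2, cc$nm2$y, cc$nm2$rs)
    # attention
    dAO <- dHmid
    dO <- .lin_bwd(cc$O, dAO, W$wo, ad$wo, sc, grads, l, "wo")
    dQ <- matrix(0, B * n, d)
    dK <- matrix(0, B * n, d)
    dV <- matrix(0, B * n, d)
    for (h in seq_len(nh)) {
      ch <- ((h - 1L) * hd + 1L):(h * hd)
      for (b in seq_len(B)) {
        rb <- rows_b(b)
        P <- cc$Ps[[(h - 1L) * B + b]]
        dOh <- dO[rb, ch, drop = FALSE]
        dP <- tcrossprod(dOh, cc$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- crossprod(P, dOh)
        dSc <- P * (dP - .rowSums(dP * P, n, n)) * inv_sqrt_hd
        dQ[rb, ch] <- dSc %*% cc$K[rb, ch, drop = FALSE]
        dK[rb, ch] <- crossprod(dSc, cc$Q[rb, ch, drop = FALSE])
      }
      dQ[, ch] <- .rope_apply(dQ[, ch, drop = FALSE], co, -si)
      dK[, ch] <- .rope_apply(dK[, ch, drop = FALSE], co, -si)
    }
    a <- cc$nm1$y
    da <- .lin_bwd(a, dQ, W$wq, ad$wq, sc, grads, l, "wq") +
      .lin_bwd(a, dK, W$wk, ad$wk, sc, grads, l, "wk") +
      .lin_bwd(a, dV, W$wv, ad$wv, sc, grads, l, "wv")
    dH <- dHmid + .rmsnorm_bwd(da, cc$nm1$y, cc$nm1$rs)
  }
  list(loss = loss, n_tokens = B * n, grads = grads$g)
}

#' Mean per-token negative log-likelihood of labeled records
#'
#' Forward-only evaluation of the model's cross-entropy on a set of
#' germline-labeled sequences (lower is better; `exp` of it is perplexity).
#'
#' @param model A `nano_generator`.
#' @param records A labeled `nano_records` data frame.
#' @return Mean negative log-likelihood per token.
#' @export
sequence_nll <- function(model, records) {
  toks <- .tokenize_records(model, records)
  lens <- lengths(toks)
  tot <- 0
  ntok <- 0
  for (L in unique(lens)) {
    grp <- which(lens == L)
    ids <- do.call(rbind, toks[grp])
    out <- .model_pass(model, ids, backward = FALSE)
    tot <- tot + out$loss * out$n_tokens
    ntok <- ntok + out$n_tokens
  }
  tot / ntok
}

#' Train the LoRA adapters on a labeled dataset
#'
#' Tokenizes each record as `[germline-tag][begin]residues[end]`, minimizes
#' next-token cross-entropy with Adam, and updates only the adapter (A, B)
#' matrices; the base weights are frozen and their checksum is recorded
#' before and after training. Reproducible from `seed` (batch shuffling is
#' the only randomness). Batches group sequences of equal length.
#'
#' @param model A `nano_generator` from [attach_lora()].
#' @param dataset A `curated_dataset` (its `train` split is used) or a
#'   labeled `nano_records` data frame.
#' @param epochs,lr,batch_size Optimization settings.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return The trained `nano_generator`, with `training_log` (per-epoch mean
#'   loss) and `base_checksum$before` / `base_checksum$after`.
#' @export
train_generator <- function(model, dataset, epochs = 4L, lr = 2.5e-3,
                            batch_size = 16L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "nano_generator"))
  records <- if (inherits(dataset, "curated_dataset")) dataset$train else dataset
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  toks <- .tokenize_records(model, records)
  lens <- lengths(toks)
  checksum_before <- base_checksum_of(model$base)

  # Adam state mirroring the adapter structure
  mstate <- lapply(model$adapters, function(l) {
    lapply(l, function(ab) list(mA = ab$A * 0, vA = ab$A * 0,
                                mB = ab$B * 0, vB = ab$B * 0))
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  log <- numeric(epochs)

  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      # equal-length batches, order shuffled each epoch
      batches <- list()
      for (L in unique(lens)) {
        grp <- sample(which(lens == L))
        nb <- ceiling(length(grp) / batch_size)
        for (k in seq_len(nb)) {
          batches[[length(batches) + 1L]] <-
            grp[((k - 1L) * batch_size + 1L):min(k * batch_size, length(grp))]
        }
      }
      batches <- batches[sample(length(batches))]
      tot <- 0; ntok <- 0
      for (bt in batches) {
        ids <- do.call(rbind, toks[bt])
        out <- .model_pass(model, ids, backward = TRUE)
        tot <- tot + out$loss * out$n_tokens
        ntok <- ntok + out$n_tokens
        step <- step + 1L
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (l in seq_along(model$adapters)) {
          for (t in names(model$adapters[[l]])) {
            g <- out$grads[[l]][[t]]
            st <- mstate[[l]][[t]]
            st$mA <- beta1 * st$mA + (1 - beta1) * g$A
            st$vA <- beta2 * st$vA + (1 - beta2) * g$A^2
            st$mB <- beta1 * st$mB + (1 - beta1) * g$B
            st$vB <- beta2 * st$vB + (1 - beta2) * g$B^2
            mstate[[l]][[t]] <- st
            model$adapters[[l]][[t]]$A <-
              model$adapters[[l]][[t]]$A -
              lr * (st$mA / bc1) / (sqrt(st$vA / bc2) + eps)
            model$adapters[[l]][[t]]$B <-
              model$adapters[[l]][[t]]$B -
              lr * (st$mB / bc1) / (sqrt(st$vB / bc2) + eps)
          }
        }
      }
      log[ep] <- tot / ntok
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, log[ep]))
    }
  })

  model$trained <- TRUE
  model$training_log <- log
  model$base_checksum <- list(before = checksum_before,
                              after = base_checksum_of(model$base))
  model
}
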