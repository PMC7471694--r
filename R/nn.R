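# Native training engine for the benchmark architectures.
#
# Inputs are integer code matrices (rows = sequences, columns = positions,
# values 1..A1 with 1 = pad) rather than materialised one-hot arrays: a
# convolution over a one-hot input is a column lookup into the kernel
# weights, and a dense layer over flattened one-hot input is a scatter of
# ones, so both directions avoid forming the binary tensors. Convolutions
# are length-preserving (stride 1, zero-filled boundaries), as the
# activation-analysis stage requires filters x T activation maps.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# initialise parameters for an architecture; RNG state is the caller's
nn_init_params <- function(arch, A1, T_len, n_out) {
  P <- if (arch$name == "stack_conv") arch$n_parallel_convs else if (arch$name == "1_conv") 1L else 0L
  K <- arch$conv_kernel
  F_ <- arch$conv_filters
  conv <- NULL
  if (P > 0) {
    conv <- lapply(seq_len(P), function(p) {
      list(
        W = lapply(seq_len(K), function(k) glorot(F_, A1, A1 * K, F_)),
        b = numeric(F_)
      )
    })
  }
  d0 <- if (P > 0) P * F_ * T_len else A1 * T_len
  sizes <- c(d0, arch$dense_sizes)
  dense <- lapply(seq_along(arch$dense_sizes), function(i) {
    list(W = glorot(sizes[i + 1], sizes[i], sizes[i], sizes[i + 1]), b = numeric(sizes[i + 1]))
  })
  last <- sizes[length(sizes)]
  out <- list(W = glorot(n_out, last, last, n_out), b = numeric(n_out))
  list(conv = conv, dense = dense, out = out)
}

# shifted lookup indices for a "same" convolution: list over kernel taps of
# integer vectors of length T*B indexing columns of [W | 0]
conv_indices <- function(St, K, A1) {
  T_len <- nrow(St)
  B <- ncol(St)
  left <- (K - 1L) %/% 2L
  lapply(seq_len(K), function(k) {
    shift <- k - 1L - left
    idx <- matrix(A1 + 1L, T_len, B)
    j <- seq_len(T_len)
    ok <- j + shift >= 1L & j + shift <= T_len
    idx[ok, ] <- St[j[ok] + shift, , drop = FALSE]
    as.vector(idx)
  })
}

nn_forward <- function(params, arch, S, n_out, A1, training = FALSE) {
  B <- nrow(S)
  T_len <- ncol(S)
  St <- t(S)
  cache <- list(B = B, T_len = T_len)
  if (!is.null(params$conv)) {
    K <- length(params$conv[[1]]$W)
    F_ <- nrow(params$conv[[1]]$W[[1]])
    idx <- conv_indices(St, K, A1)
    Hs <- vector("list", length(params$conv))
    masks <- vector("list", length(params$conv))
    for (p in seq_along(params$conv)) {
      Wk <- params$conv[[p]]$W
      Z <- matrix(params$conv[[p]]$b, F_, T_len * B)
      for (k in seq_len(K)) {
        Z <- Z + cbind(Wk[[k]], 0)[, idx[[k]], drop = FALSE]
      }
      masks[[p]] <- Z > 0
      Hs[[p]] <- relu(Z)
    }
    H_all <- if (length(Hs) == 1) Hs[[1]] else do.call(rbind, Hs)
    X <- matrix(H_all, nrow = length(params$conv) * F_ * T_len, ncol = B)
    cache$conv <- list(idx = idx, masks = masks, F_ = F_, K = K, A1 = A1)
  } else {
    ridx <- (rep(seq_len(T_len), times = B) - 1L) * A1 + as.vector(St)
    X <- matrix(0, A1 * T_len, B)
    X[cbind(ridx, rep(seq_len(B), each = T_len))] <- 1
  }
  cache$X <- X
  H <- X
  As <- vector("list", length(params$dense))
  zmask <- vector("list", length(params$dense))
  dmask <- vector("list", length(params$dense))
  for (i in seq_along(params$dense)) {
    Z <- params$dense[[i]]$W %*% H + params$dense[[i]]$b
    zmask[[i]] <- Z > 0
    A <- relu(Z)
    if (training && arch$dropout > 0) {
      m <- matrix(
        (stats::runif(length(A)) >= arch$dropout) / (1 - arch$dropout),
        nrow(A), ncol(A)
      )
      A <- A * m
      dmask[[i]] <- m
    }
    As[[i]] <- A
    H <- A
  }
  Zo <- params$out$W %*% H + params$out$b
  probs <- if (n_out == 1L) {
    stats::plogis(Zo)
  } else {
    Zo <- Zo - rep(apply(Zo, 2, max), each = n_out)
    E <- exp(Zo)
    E / rep(colSums(E), each = n_out)
  }
  cache$As <- As
  cache$zmask <- zmask
  cache$dmask <- dmask
  list(probs = probs, cache = cache)
}

# gradients of mean cross-entropy; Y is n_out x B (one-hot or 0/1 row)
nn_backward <- function(params, arch, cache, probs, Y) {
  B <- cache$B
  T_len <- cache$T_len
  nd <- length(params$dense)
  grads <- list(conv = NULL, dense = vector("list", nd), out = NULL)
  dZ <- (probs - Y) / B
  H_last <- if (nd > 0) cache$As[[nd]] else cache$X
  grads$out <- list(W = dZ %*% t(H_last), b = rowSums(dZ))
  dA <- t(params$out$W) %*% dZ
  for (i in rev(seq_len(nd))) {
    if (!is.null(cache$dmask[[i]])) dA <- dA * cache$dmask[[i]]
    dZ <- dA * cache$zmask[[i]]
    H_prev <- if (i > 1) cache$As[[i - 1]] else cache$X
    grads$dense[[i]] <- list(W = dZ %*% t(H_prev), b = rowSums(dZ))
    dA <- t(params$dense[[i]]$W) %*% dZ
  }
  if (!is.null(params$conv)) {
    cv <- cache$conv
    P <- length(params$conv)
    dH_all <- matrix(dA, nrow = P * cv$F_, ncol = T_len * B)
    grads$conv <- vector("list", P)
    for (p in seq_len(P)) {
      rows <- (p - 1L) * cv$F_ + seq_len(cv$F_)
      dZc <- dH_all[rows, , drop = FALSE] * cv$masks[[p]]
      gW <- vector("list", cv$K)
      tdZ <- t(dZc)
      for (k in seq_len(cv$K)) {
        g <- rowsum(tdZ, group = cv$idx[[k]])
        sym <- as.integer(rownames(g))
        W_g <- matrix(0, cv$F_, cv$A1)
        keep <- sym <= cv$A1
        if (any(keep)) W_g[, sym[keep]] <- t(g[keep, , drop = FALSE])
        gW[[k]] <- W_g
      }
      grads$conv[[p]] <- list(W = gW, b = rowSums(dZc))
    }
  }
  grads
}

# recursive map over parallel parameter trees (numeric-array leaves)
tree_mapn <- function(trees, f) {
  first <- trees[[1]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      if (is.null(first[[i]])) next
      out[[i]] <- tree_mapn(lapply(trees, `[[`, i), f)
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros <- function(tree) tree_mapn(list(tree), function(x) x * 0)

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_mapn(list(state$m, grads), function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_mapn(list(state$v, grads), function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_mapn(
    list(params, state$m, state$v),
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps)
  )
  list(params = params, state = state)
}

ce_loss <- function(probs, Y, n_out) {
  eps <- 1e-12
  if (n_out == 1L) {
    -mean(Y * log(probs + eps) + (1 - Y) * log(1 - probs + eps))
  } else {
    -mean(colSums(Y * log(probs + eps)))
  }
}

nn_accuracy <- function(probs, y, n_out) {
  if (n_out == 1L) {
    mean((drop(probs) > 0.5) == (y > 0.5))
  } else {
    mean(max.col(t(probs), ties.method = "first") == y)
  }
}

as_target <- function(y, n_out) {
  if (n_out == 1L) {
    matrix(as.numeric(y), nrow = 1)
  } else {
    Y <- matrix(0, n_out, length(y))
    Y[cbind(y, seq_along(y))] <- 1
    Y
  }
}

# full training loop; returns params of the best-validation-accuracy epoch
nn_fit <- function(params, arch, S_tr, y_tr, S_val, y_val, n_out, A1, config) {
  n <- nrow(S_tr)
  history <- vector("list", config$epochs)
  best_acc <- -Inf
  best_params <- params
  best_epoch <- NA_integer_
  state <- list(t = 0L, m = tree_zeros(params), v = tree_zeros(params))
  withr::with_seed(derive_seed(config$seed, "fit"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        take <- ord[s:min(s + config$batch_size - 1L, n)]
        Sb <- S_tr[take, , drop = FALSE]
        Yb <- as_target(y_tr[take], n_out)
        fw <- nn_forward(params, arch, Sb, n_out, A1, training = TRUE)
        loss <- ce_loss(fw$probs, Yb, n_out)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss * length(take)
        g <- nn_backward(params, arch, fw$cache, fw$probs, Yb)
        upd <- adam_step(params, g, state,
          lr = config$learning_rate,
          beta1 = config$beta1, beta2 = config$beta2
        )
        params <- upd$params
        state <- upd$state
      }
      val_probs <- nn_forward(params, arch, S_val, n_out, A1)$probs
      val_acc <- nn_accuracy(val_probs, y_val, n_out)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss / n, val_accuracy = val_acc
      )
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_params <- params
        best_epoch <- epoch
      }
    }
  })
  list(
    params = best_params, selected_epoch = best_epoch,
    history = dplyr::bind_rows(history)
  )
}
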