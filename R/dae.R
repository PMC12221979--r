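#' Disentangling autoencoder configuration
#'
#' Hyperparameters of the voxel autoencoder: a stack of strided 3-D
#' convolutions halving the grid side per layer (32 -> 16 -> 8 -> 4 -> 2 by
#' default), a linear head to the latent space, an exactly orthogonal
#' learned latent map (Givens-product parameterization, see
#' [euler_orthogonal_map()]), and a mirrored transposed-convolution decoder
#' with a sigmoid output squashing values into \[0, 1\].
#'
#' @param latent_dim latent dimensionality (>= 2), default 6.
#' @param conv_channels channels per encoder layer (decoder mirrors them).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and batching.
#' @param loss `"bce"` (per-voxel binary likelihood) or `"mse"`.
#' @param input_side input grid side, default 32 (must be
#'   `2^length(conv_channels)` times a positive integer side of the conv
#'   trunk output).
#' @return An object of class `dae_config`.
#' @export
dae_config <- function(latent_dim = 6L, conv_channels = c(8L, 16L, 32L, 64L),
                       epochs = 40L, batch_size = 32L, learning_rate = 1e-3,
                       seed = 1L, loss = c("bce", "mse"), input_side = 32L) {
  loss <- match.arg(loss)
  stopifnot(latent_dim >= 2L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, all(conv_channels >= 1L), input_side >= 8L)
  if (input_side %% (2L^length(conv_channels)) != 0L)
    stop("input_side must be divisible by 2^length(conv_channels)")
  structure(list(latent_dim = as.integer(latent_dim),
                 conv_channels = as.integer(conv_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss = loss, input_side = as.integer(input_side)),
            class = "dae_config")
}

#' Exactly orthogonal matrix from plane-rotation angles
#'
#' Parameterizes a d x d rotation as the ordered product of Givens plane
#' rotations G(i, j, theta_ij) over all index pairs i < j (lexicographic
#' order, d (d - 1) / 2 angles; 15 for d = 6). The result is orthogonal up
#' to floating round-off by construction, for any angles, which is how the
#' latent map keeps its dimensions linearly independent throughout
#' training.
#'
#' @param angles numeric vector of length `d (d - 1) / 2`.
#' @param d dimension; inferred from `length(angles)` when omitted.
#' @return A d x d orthogonal matrix.
#' @export
euler_orthogonal_map <- function(angles, d = NULL) {
  K <- length(angles)
  d <- d %||% as.integer(round((1 + sqrt(1 + 8 * K)) / 2))
  if (d * (d - 1) / 2 != K)
    stop("euler_orthogonal_map: need d(d-1)/2 angles, got ", K)
  R <- diag(d)
  k <- 0L
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    k <- k + 1L
    cth <- cos(angles[k]); sth <- sin(angles[k])
    ci <- R[, i]; cj <- R[, j]
    R[, i] <- cth * ci + sth * cj     # right-multiply by G(i, j, theta)
    R[, j] <- -sth * ci + cth * cj
  }
  R
}

givens_pairs <- function(d) {
  out <- matrix(0L, d * (d - 1L) / 2L, 2L)
  k <- 0L
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    k <- k + 1L
    out[k, ] <- c(i, j)
  }
  out
}

# Backward pass through the Givens product: given upstream gradient dZ
# (d x B) and the input zlin, return d(angles) and d(zlin).
givens_backward <- function(angles, zlin, dZ) {
  d <- nrow(zlin)
  prs <- givens_pairs(d)
  K <- nrow(prs)
  # u[[k]] = G_k ... G_K %*% zlin  (u[[K+1]] = zlin)
  u <- vector("list", K + 1L)
  u[[K + 1L]] <- zlin
  for (k in K:1) {
    i <- prs[k, 1L]; j <- prs[k, 2L]
    cth <- cos(angles[k]); sth <- sin(angles[k])
    v <- u[[k + 1L]]
    w <- v
    w[i, ] <- cth * v[i, ] - sth * v[j, ]
    w[j, ] <- sth * v[i, ] + cth * v[j, ]
    u[[k]] <- w
  }
  dang <- numeric(K)
  wk <- dZ                              # t(G_1 .. G_{k-1}) %*% dZ
  for (k in seq_len(K)) {
    i <- prs[k, 1L]; j <- prs[k, 2L]
    cth <- cos(angles[k]); sth <- sin(angles[k])
    v <- u[[k + 1L]]
    dang[k] <- sum(wk[i, ] * (-sth * v[i, ] - cth * v[j, ])) +
               sum(wk[j, ] * (cth * v[i, ] - sth * v[j, ]))
    ti <- wk[i, ]; tj <- wk[j, ]        # advance wk by t(G_k)
    wk[i, ] <- cth * ti + sth * tj
    wk[j, ] <- -sth * ti + cth * tj
  }
  list(dangles = dang, dzlin = wk)
}

#' Build an untrained disentangling autoencoder
#'
#' Allocates and He-initializes all parameters (deterministic for a fixed
#' config seed) and precomputes the convolution index tables. The latent
#' map angles start at zero (identity rotation).
#'
#' @param config a [dae_config()].
#' @return An object of class `dae_model` with elements `config`, `params`,
#'   `geom`, `n_parameters`, `history`.
#' @export
build_dae <- function(config = dae_config()) {
  stopifnot(inherits(config, "dae_config"))
  k <- 4L; stride <- 2L; pad <- 1L
  ch <- c(1L, config$conv_channels)
  L <- length(config$conv_channels)
  sides <- config$input_side / 2L^(0:L)
  if (any(sides < 1L)) stop("conv trunk collapses below side 1")
  h_dim <- ch[L + 1L] * sides[L + 1L]^3
  if (h_dim < config$latent_dim)
    stop("latent_dim incompatible with conv head size ", h_dim)
  idx <- lapply(seq_len(L), function(l)
    .conv_index_cpp(sides[l], k, stride, pad))
  geom <- list(k = k, k3 = k^3, sides = sides, ch = ch, L = L, idx = idx,
               h_dim = h_dim)
  params <- with_local_seed(config$seed, {
    he <- function(nr, nc, fan) matrix(rnorm(nr * nc, sd = sqrt(2 / fan)),
                                       nr, nc)
    p <- list()
    for (l in seq_len(L)) {
      fan <- ch[l] * k^3
      p[[paste0("enc_W", l)]] <- he(ch[l + 1L], fan, fan)
      p[[paste0("enc_b", l)]] <- numeric(ch[l + 1L])
    }
    p$fc_W <- he(config$latent_dim, h_dim, h_dim)
    p$fc_b <- numeric(config$latent_dim)
    p$angles <- numeric(config$latent_dim * (config$latent_dim - 1L) / 2L)
    p$dec_fc_W <- he(h_dim, config$latent_dim, config$latent_dim)
    p$dec_fc_b <- numeric(h_dim)
    for (l in seq_len(L)) {
      fan <- ch[l + 1L] * k^3
      p[[paste0("dec_W", l)]] <- he(ch[l + 1L], ch[l] * k^3, fan)
      p[[paste0("dec_b", l)]] <- numeric(ch[l])
    }
    p
  })
  n_par <- sum(vapply(params, length, 1L))
  structure(list(config = config, params = params, geom = geom,
                 n_parameters = n_par, history = NULL, trained = FALSE),
            class = "dae_model")
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf(
    "<dae_model> %d^3 -> %d-D latent (orthogonal map), %s params, %s\n",
    x$config$input_side, x$config$latent_dim,
    format(x$n_parameters, big.mark = ","),
    if (x$trained) sprintf("trained %d epochs", length(x$history$loss))
    else "untrained"))
  invisible(x)
}

# Forward pass. X: (side^3 x B) matrix of grids in [0, 1].
# Returns activations needed for backprop when cache = TRUE.
dae_forward <- function(model, X, cache = FALSE) {
  g <- model$geom; p <- model$params
  B <- ncol(X)
  A <- list(X)
  for (l in seq_len(g$L)) {
    n_out <- g$sides[l + 1L]^3
    P <- .im2col_cpp(A[[l]], g$idx[[l]], g$ch[l], g$k3, n_out)
    Zc <- p[[paste0("enc_W", l)]] %*% P + p[[paste0("enc_b", l)]]
    A[[l + 1L]] <- matrix(pmax(Zc, 0), g$ch[l + 1L] * n_out, B)
  }
  h <- A[[g$L + 1L]]
  zlin <- p$fc_W %*% h + p$fc_b
  Rm <- euler_orthogonal_map(p$angles, model$config$latent_dim)
  z <- Rm %*% zlin
  D <- list()
  D[[g$L + 1L]] <- matrix(pmax(p$dec_fc_W %*% z + p$dec_fc_b, 0), g$h_dim, B)
  for (l in g$L:1) {
    n_small <- g$sides[l + 1L]^3
    Xc <- matrix(D[[l + 1L]], g$ch[l + 1L], n_small * B)
    Pd <- crossprod(p[[paste0("dec_W", l)]], Xc)
    Y <- .col2im_cpp(Pd, g$idx[[l]], g$ch[l], g$k3, n_small, g$sides[l]^3, B)
    Y <- Y + rep(p[[paste0("dec_b", l)]], times = g$sides[l]^3)
    D[[l]] <- if (l == 1L) 1 / (1 + exp(-Y)) else matrix(pmax(Y, 0), nrow(Y), B)
  }
  out <- list(recon = D[[1L]], z = z, zlin = zlin, Rm = Rm)
  if (cache) { out$A <- A; out$D <- D }
  out
}

dae_loss <- function(recon, X, loss) {
  eps <- 1e-7
  if (loss == "bce")
    -mean(X * log(recon + eps) + (1 - X) * log(1 - recon + eps))
  else mean((recon - X)^2)
}

# Backward pass; fw must come from dae_forward(cache = TRUE).
dae_backward <- function(model, X, fw) {
  g <- model$geom; p <- model$params
  B <- ncol(X)
  N <- length(X)
  gr <- list()
  recon <- fw$recon
  dY <- if (model$config$loss == "bce") (recon - X) / N
        else 2 * (recon - X) * recon * (1 - recon) / N   # through sigmoid
  dD <- dY                                               # grad at decoder out
  for (l in seq_len(g$L)) {
    n_small <- g$sides[l + 1L]^3
    dv <- matrix(rowSums(dD), g$ch[l], g$sides[l]^3)
    gr[[paste0("dec_b", l)]] <- rowSums(dv)
    dPd <- .im2col_cpp(dD, g$idx[[l]], g$ch[l], g$k3, n_small)
    Xc <- matrix(fw$D[[l + 1L]], g$ch[l + 1L], n_small * B)
    gr[[paste0("dec_W", l)]] <- tcrossprod(Xc, dPd)
    dXc <- p[[paste0("dec_W", l)]] %*% dPd
    dD <- matrix(dXc, g$ch[l + 1L] * n_small, B)
    if (l < g$L) dD <- dD * (fw$D[[l + 1L]] > 0)
  }
  dD0 <- dD * (fw$D[[g$L + 1L]] > 0)
  gr$dec_fc_W <- tcrossprod(dD0, fw$z)
  gr$dec_fc_b <- rowSums(dD0)
  dz <- crossprod(p$dec_fc_W, dD0)
  gb <- givens_backward(p$angles, fw$zlin, dz)
  gr$angles <- gb$dangles
  dzlin <- gb$dzlin
  h <- fw$A[[g$L + 1L]]
  gr$fc_W <- tcrossprod(dzlin, h)
  gr$fc_b <- rowSums(dzlin)
  dA <- crossprod(p$fc_W, dzlin)
  for (l in g$L:1) {
    n_out <- g$sides[l + 1L]^3
    dA <- dA * (fw$A[[l + 1L]] > 0)
    dZc <- matrix(dA, g$ch[l + 1L], n_out * B)
    gr[[paste0("enc_b", l)]] <- rowSums(dZc)
    P <- .im2col_cpp(fw$A[[l]], g$idx[[l]], g$ch[l], g$k3, n_out)
    gr[[paste0("enc_W", l)]] <- tcrossprod(dZc, P)
    if (l > 1L) {
      dP <- crossprod(p[[paste0("enc_W", l)]], dZc)
      dA <- .col2im_cpp(dP, g$idx[[l]], g$ch[l], g$k3, n_out,
                        g$sides[l]^3, B)
    }
  }
  gr
}

as_grid_matrix <- function(grids, side) {
  if (is.matrix(grids)) {
    if (nrow(grids) != side^3)
      stop("grid side must be ", side, " (got ", round(nrow(grids)^(1/3)),
           ")")
    return(grids)
  }
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  X <- vapply(grids, function(gr) {
    v <- if (inherits(gr, "voxel_grid")) gr$values else gr
    if (!all(dim(v) == side)) stop("grid side must be ", side)
    as.numeric(v)
  }, numeric(side^3))
  matrix(X, nrow = side^3)
}

#' Train the disentangling autoencoder
#'
#' Minibatch Adam on the per-voxel reconstruction loss. The latent map
#' stays exactly orthogonal at every step because only its angles are
#' updated; the per-epoch maximum Gram deviation `max |R'R - I|` is logged
#' alongside the loss. Training aborts on a non-finite loss. Fixed seed
#' gives a reproducible parameter trajectory.
#'
#' @param model a [build_dae()] model.
#' @param grids list of side-32 [voxel_grid()]s (or a `side^3 x n` matrix).
#' @param epochs,batch_size,learning_rate optional overrides of the
#'   model config.
#' @param verbose print per-epoch loss.
#' @return The trained `dae_model` with a `history` data.frame
#'   (`epoch`, `loss`, `gram_dev`).
#' @export
train_dae <- function(model, grids, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, verbose = FALSE) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  X <- as_grid_matrix(grids, cfg$input_side)
  n <- ncol(X)
  if (n == 0L) stop("train_dae: empty dataset")
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- mstate
  step <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     gram_dev = numeric(0))
  with_local_seed(cfg$seed + 101L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (s in seq(1L, n, by = batch_size)) {
        ids <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- X[, ids, drop = FALSE]
        fw <- dae_forward(model, Xb, cache = TRUE)
        lo <- dae_loss(fw$recon, Xb, cfg$loss)
        if (!is.finite(lo))
          stop("train_dae: non-finite loss at epoch ", ep,
               " (step ", step + 1L, ")")
        gr <- dae_backward(model, Xb, fw)
        step <- step + 1L
        for (nm in names(model$params)) {
          gnm <- gr[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gnm
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gnm^2
          mhat <- mstate[[nm]] / (1 - b1^step)
          vhat <- vstate[[nm]] / (1 - b2^step)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + lo * length(ids)
        ep_n <- ep_n + length(ids)
      }
      Rm <- euler_orthogonal_map(model$params$angles, cfg$latent_dim)
      gd <- max(abs(crossprod(Rm) - diag(cfg$latent_dim)))
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / ep_n,
                                     gram_dev = gd))
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f  gram_dev %.2e", ep,
                        ep_loss / ep_n, gd))
    }
  })
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Encode voxel grids into the latent space
#'
#' @param model a `dae_model`.
#' @param grids a [voxel_grid()], list of them, or `side^3 x n` matrix.
#' @return An n x latent_dim matrix of latent vectors (columns
#'   `Dim_0 .. Dim_{d-1}`); a single grid gives a 1-row matrix.
#' @export
encode <- function(model, grids) {
  X <- as_grid_matrix(grids, model$config$input_side)
  out <- matrix(NA_real_, ncol(X), model$config$latent_dim)
  bs <- 64L
  for (s in seq(1L, ncol(X), by = bs)) {
    ids <- s:min(s + bs - 1L, ncol(X))
    out[ids, ] <- t(dae_forward(model, X[, ids, drop = FALSE])$z)
  }
  colnames(out) <- paste0("Dim_", seq_len(model$config$latent_dim) - 1L)
  out
}

#' Decode latent vectors into voxel grids
#'
#' @param model a `dae_model`.
#' @param z a latent vector, or n x latent_dim matrix.
#' @return A [voxel_grid()] (single vector) or list of them, values in
#'   \[0, 1\].
#' @export
decode <- function(model, z) {
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, ncol = 1L) else t(as.matrix(z))
  if (nrow(Z) != model$config$latent_dim)
    stop("decode: latent dimension mismatch")
  g <- model$geom; p <- model$params
  B <- ncol(Z)
  D <- matrix(pmax(p$dec_fc_W %*% Z + p$dec_fc_b, 0), g$h_dim, B)
  for (l in g$L:1) {
    n_small <- g$sides[l + 1L]^3
    Xc <- matrix(D, g$ch[l + 1L], n_small * B)
    Pd <- crossprod(p[[paste0("dec_W", l)]], Xc)
    Y <- .col2im_cpp(Pd, g$idx[[l]], g$ch[l], g$k3, n_small, g$sides[l]^3, B)
    Y <- Y + rep(p[[paste0("dec_b", l)]], times = g$sides[l]^3)
    D <- if (l == 1L) 1 / (1 + exp(-Y)) else matrix(pmax(Y, 0), nrow(Y), B)
  }
  side <- model$config$input_side
  grids <- lapply(seq_len(B), function(i)
    voxel_grid(array(D[, i], dim = rep(side, 3L)), origin = c(-1, -1, -1),
               spacing = 2 / side, binary = FALSE))
  if (single) grids[[1L]] else grids
}

#' Save / load a trained model
#'
#' Single-file archive: a one-line JSON header (config and parameter
#' shapes) followed by all parameters as a little-endian double block.
#'
#' @param model a `dae_model`.
#' @param path file path.
#' @return `path` invisibly; `load_dae()` returns the model.
#' @export
save_dae <- function(model, path) {
  p <- model$params
  shapes <- lapply(p, function(x) if (is.matrix(x)) dim(x) else length(x))
  hdr <- jsonlite::toJSON(list(config = unclass(model$config),
                               shapes = shapes,
                               trained = model$trained), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
  for (x in p) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_dae
#' @export
load_dae <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw == charToRaw("\n"))[1L]
  hdr <- jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)]))
  cfg <- do.call(dae_config, hdr$config[setdiff(names(hdr$config), NULL)])
  model <- build_dae(cfg)
  vals <- readBin(raw[-seq_len(nl)], "numeric",
                  n = model$n_parameters, size = 8L, endian = "little")
  off <- 0L
  for (nm in names(model$params)) {
    len <- length(model$params[[nm]])
    x <- vals[(off + 1L):(off + len)]
    if (is.matrix(model$params[[nm]]))
      x <- matrix(x, nrow(model$params[[nm]]), ncol(model$params[[nm]]))
    model$params[[nm]] <- x
    off <- off + len
  }
  model$trained <- isTRUE(hdr$trained)
  model
}
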