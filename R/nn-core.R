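# Minimal neural-network engine: dense reverse-mode autodiff over a small
# set of image ops (convolution, ReLU/sigmoid, 2x2 max pooling, nearest
# upsampling, channel concatenation/pooling, dense layers, dropout).
# Tensors are plain arrays [h, w, channels]; convolutions are realized as
# k^2 shifted-slice matrix products so all heavy lifting is BLAS.
# Everything here is internal; the exported network constructors live in
# segnet.R and classify.R.

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero gradient/moment buffer with exactly the parameter's shape (plain
# numeric for vector parameters, so updates never promote them to 1-d
# arrays)
zeros_like <- function(p) {
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
}

new_tape <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$pgrad <- lapply(params, zeros_like)
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

add_node <- function(tp, val, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- backfn
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

nd_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

pgrad_accum <- function(tp, name, g) {
  tp$pgrad[[name]] <- tp$pgrad[[name]] + g
}

tape_backward <- function(tp, out, dout) {
  nd_accum(out, dout)
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(tp$pgrad)
}

t_input <- function(tp, val) add_node(tp, val)

# ---- convolution -----------------------------------------------------------

conv_fwd <- function(x, W, b) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  if (k == 1L) {
    out <- matrix(x, h * w, cin) %*% matrix(W, cin, cout)
  } else {
    r <- (k - 1L) %/% 2L
    xp <- array(0, c(h + 2L * r, w + 2L * r, cin))
    xp[r + seq_len(h), r + seq_len(w), ] <- x
    out <- matrix(0, h * w, cout)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      slice <- matrix(xp[i:(i + h - 1L), j:(j + w - 1L), ], h * w, cin)
      out <- out + slice %*% matrix(W[i, j, , ], cin, cout)
    }
  }
  out <- sweep(out, 2L, b, "+")
  array(out, c(h, w, cout))
}

conv_bwd <- function(x, W, dout) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  dm <- matrix(dout, h * w, cout)
  db <- colSums(dm)
  dW <- array(0, dim(W))
  if (k == 1L) {
    xm <- matrix(x, h * w, cin)
    dW[1, 1, , ] <- crossprod(xm, dm)
    dx <- array(dm %*% t(matrix(W, cin, cout)), c(h, w, cin))
  } else {
    r <- (k - 1L) %/% 2L
    xp <- array(0, c(h + 2L * r, w + 2L * r, cin))
    xp[r + seq_len(h), r + seq_len(w), ] <- x
    dxp <- array(0, dim(xp))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- i:(i + h - 1L); ci <- j:(j + w - 1L)
      slice <- matrix(xp[ri, ci, ], h * w, cin)
      dW[i, j, , ] <- crossprod(slice, dm)
      dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] +
        array(dm %*% t(matrix(W[i, j, , ], cin, cout)), c(h, w, cin))
    }
    dx <- dxp[r + seq_len(h), r + seq_len(w), , drop = FALSE]
  }
  list(dx = array(dx, c(h, w, cin)), dW = dW, db = db)
}

t_conv <- function(tp, x, wname, bname) {
  W <- tp$params[[wname]]; b <- tp$params[[bname]]
  val <- conv_fwd(x$val, W, b)
  add_node(tp, val, function(g) {
    bw <- conv_bwd(x$val, W, g)
    pgrad_accum(tp, wname, bw$dW)
    pgrad_accum(tp, bname, bw$db)
    nd_accum(x, bw$dx)
  })
}

# ---- pointwise nonlinearities ---------------------------------------------

t_relu <- function(tp, x) {
  val <- pmax(x$val, 0)
  add_node(tp, val, function(g) nd_accum(x, g * (x$val > 0)))
}

t_sigmoid <- function(tp, x) {
  val <- 1 / (1 + exp(-x$val))
  add_node(tp, val, function(g) nd_accum(x, g * val * (1 - val)))
}

# ---- pooling / resampling --------------------------------------------------

t_pool2 <- function(tp, x) {
  d <- dim(x$val); h <- d[1]; w <- d[2]; ch <- d[3]
  if (h %% 2L || w %% 2L) stop_config("max-pool needs even spatial dims, got %dx%d", h, w)
  oi <- seq(1L, h, 2L); ei <- seq(2L, h, 2L)
  oj <- seq(1L, w, 2L); ej <- seq(2L, w, 2L)
  a1 <- x$val[oi, oj, , drop = FALSE]; a2 <- x$val[ei, oj, , drop = FALSE]
  a3 <- x$val[oi, ej, , drop = FALSE]; a4 <- x$val[ei, ej, , drop = FALSE]
  val <- pmax(a1, a2, a3, a4)
  idx <- ifelse(a1 >= a2 & a1 >= a3 & a1 >= a4, 1L,
         ifelse(a2 >= a3 & a2 >= a4, 2L, ifelse(a3 >= a4, 3L, 4L)))
  add_node(tp, val, function(g) {
    dx <- array(0, d)
    route <- function(which, ri, ci) {
      tmp <- array(0, dim(val))
      sel <- idx == which
      tmp[sel] <- g[sel]
      dx[ri, ci, ] <<- dx[ri, ci, ] + tmp
    }
    route(1L, oi, oj); route(2L, ei, oj); route(3L, oi, ej); route(4L, ei, ej)
    nd_accum(x, dx)
  })
}

t_up2 <- function(tp, x) {
  d <- dim(x$val); h <- d[1]; w <- d[2]
  val <- x$val[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
  add_node(tp, val, function(g) {
    oi <- seq(1L, 2L * h, 2L); ei <- seq(2L, 2L * h, 2L)
    oj <- seq(1L, 2L * w, 2L); ej <- seq(2L, 2L * w, 2L)
    nd_accum(x, g[oi, oj, , drop = FALSE] + g[ei, oj, , drop = FALSE] +
                g[oi, ej, , drop = FALSE] + g[ei, ej, , drop = FALSE])
  })
}

t_concat <- function(tp, xs) {
  d <- dim(xs[[1]]$val)
  chans <- vapply(xs, function(x) dim(x$val)[3], 0L)
  val <- array(unlist(lapply(xs, function(x) x$val), use.names = FALSE),
               c(d[1], d[2], sum(chans)))
  add_node(tp, val, function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      nd_accum(xs[[i]], g[, , at + seq_len(chans[i]), drop = FALSE])
      at <- at + chans[i]
    }
  })
}

# multiply feature stack F (h,w,c) by single-channel map alpha (h,w,1)
t_gate_mul <- function(tp, f, alpha) {
  a <- alpha$val[, , 1]
  ch <- dim(f$val)[3]
  val <- f$val * as.vector(a)   # broadcast over channels (column-major)
  add_node(tp, val, function(g) {
    nd_accum(f, g * as.vector(a))
    da <- apply(g * f$val, c(1, 2), sum)
    nd_accum(alpha, array(da, c(dim(da), 1L)))
  })
}

# channel-wise average and max pooling: (h,w,c) -> (h,w,2) [avg; max]
t_chanpool <- function(tp, x) {
  ch <- dim(x$val)[3]
  avg <- apply(x$val, c(1, 2), mean)
  mx <- apply(x$val, c(1, 2), max)
  amax <- apply(x$val, c(1, 2), which.max)
  val <- array(c(avg, mx), c(dim(avg), 2L))
  add_node(tp, val, function(g) {
    ga <- g[, , 1] / ch
    gm <- g[, , 2]
    dx <- array(rep(ga, ch), dim(x$val))
    # route max gradient to the argmax channel
    h <- dim(x$val)[1]; w <- dim(x$val)[2]
    lin <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h), as.vector(amax))
    dx[lin] <- dx[lin] + as.vector(gm)
    nd_accum(x, dx)
  })
}

t_flatten <- function(tp, x) {
  d <- dim(x$val)
  add_node(tp, as.vector(x$val), function(g) nd_accum(x, array(g, d)))
}

t_dense <- function(tp, x, wname, bname) {
  W <- tp$params[[wname]]; b <- tp$params[[bname]]
  val <- as.vector(W %*% as.vector(x$val)) + as.vector(b)
  add_node(tp, val, function(g) {
    pgrad_accum(tp, wname, outer(g, x$val))
    pgrad_accum(tp, bname, g)
    nd_accum(x, as.vector(crossprod(W, g)))
  })
}

t_dropout <- function(tp, x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$val)) >= rate) / (1 - rate)
  dim(keep) <- dim(x$val)
  add_node(tp, x$val * keep, function(g) nd_accum(x, g * keep))
}

t_add <- function(tp, a, b) {
  add_node(tp, a$val + b$val, function(g) { nd_accum(a, g); nd_accum(b, g) })
}

# ---- parameter initialization and optimizer --------------------------------

init_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout))
}

init_dense <- function(nin, nout) {
  sd <- sqrt(2 / nin)
  matrix(stats::rnorm(nin * nout, 0, sd), nout, nin)
}

adam_init <- function(params) {
  list(m = lapply(params, zeros_like),
       v = lapply(params, zeros_like),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- losses ----------------------------------------------------------------

# Compound binary cross-entropy + soft-Dice loss on a probability map.
# Returns loss value and gradient with respect to the probabilities.
bce_dice_loss <- function(p, y, eps = 1e-7) {
  n <- length(p)
  pc <- clamp(p, eps, 1 - eps)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dbce <- (-(y / pc) + (1 - y) / (1 - pc)) / n
  sp <- sum(p); sy <- sum(y); si <- sum(p * y)
  denom <- sp + sy + eps
  dice <- 2 * si / denom
  ddice_dp <- (2 * y * denom - 2 * si) / denom^2
  list(loss = bce + (1 - dice), grad = dbce - ddice_dp)
}

# Softmax cross-entropy on a logit vector; y is the 1-based class index.
softmax_ce_loss <- function(z, y) {
  p <- exp(z - max(z)); p <- p / sum(p)
  g <- p
  g[y] <- g[y] - 1
  list(loss = -log(max(p[y], 1e-12)), grad = g, prob = p)
}
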