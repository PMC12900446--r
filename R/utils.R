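#' @keywords internal
"_PACKAGE"

# Numerically stable softmax (max-subtraction).
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise stable softmax for a matrix.
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# Backward of y = softmax(x) given dL/dy; returns dL/dx.
softmax_backward <- function(w, dw) {
  w * (dw - sum(dw * w))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# ---- parameter trees -------------------------------------------------------
# Model parameters are nested lists whose leaves are numeric arrays. The
# helpers below apply functions leaf-wise so the optimizer and the
# finite-difference checker can treat any model uniformly.

is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree) {
  if (is_param_leaf(tree)) return(f(tree))
  lapply(tree, function(x) tree_map(f, x))
}

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
  out
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# Flatten leaves into a single numeric vector (deterministic order) and back.
tree_flatten <- function(tree) {
  if (is_param_leaf(tree)) return(as.numeric(tree))
  unlist(lapply(tree, tree_flatten), use.names = FALSE)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  rebuild <- function(x) {
    if (is_param_leaf(x)) {
      n <- length(x)
      out <- x
      out[] <- values[(pos + 1L):(pos + n)]
      pos <<- pos + n
      return(out)
    }
    lapply(x, rebuild)
  }
  out <- rebuild(tree)
  stopifnot(pos == length(values))
  out
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(
    m = tree_zeros_like(params),
    v = tree_zeros_like(params),
    t = 0L
  )
}

# Decoupled weight decay; decay is applied only to leaves whose name ends in
# "W" (weight matrices), never to biases, batch-norm scales or attention
# scalers.
adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-2) {
  state$t <- state$t + 1L
  t <- state$t
  step_leaf <- function(p, g, m, v, decay) {
    m_new <- beta1 * m + (1 - beta1) * g
    v_new <- beta2 * v + (1 - beta2) * g * g
    m_hat <- m_new / (1 - beta1^t)
    v_hat <- v_new / (1 - beta2^t)
    p_new <- p - lr * (m_hat / (sqrt(v_hat) + eps) + if (decay) weight_decay * p else 0)
    list(p = p_new, m = m_new, v = v_new)
  }
  walk <- function(p, g, m, v, name) {
    if (is_param_leaf(p)) {
      decay <- grepl("(^|\\.)W[0-9]*$", name)
      return(step_leaf(p, g, m, v, decay))
    }
    out_p <- p; out_m <- m; out_v <- v
    nms <- names(p)
    for (i in seq_along(p)) {
      leaf_name <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      nm <- paste0(name, ".", leaf_name)
      res <- walk(p[[i]], g[[i]], m[[i]], v[[i]], nm)
      if (is_param_leaf(p[[i]])) {
        out_p[[i]] <- res$p; out_m[[i]] <- res$m; out_v[[i]] <- res$v
      } else {
        out_p[[i]] <- res$params; out_m[[i]] <- res$m; out_v[[i]] <- res$v
      }
    }
    list(params = out_p, m = out_m, v = out_v)
  }
  res <- walk(params, grads, state$m, state$v, "")
  list(params = res$params, state = list(m = res$m, v = res$v, t = t))
}

# Kaiming-style uniform fan-in initialization.
init_matrix <- function(n_out, n_in) {
  limit <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -limit, limit), n_out, n_in)
}
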