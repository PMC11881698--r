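# Internal numerical helpers shared across the encoder, decoder and training
# loop. None of these are exported.

# Evaluate `code` under a fixed RNG stream without disturbing the caller's
# random state. All user-facing stochastic operations funnel through this so
# that a `seed` argument fully determines their output.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Elementwise nonlinearities available to the encoder. Kept as a lookup so the
# activation is a plain config string.
.activations <- list(
  elu = list(
    f = function(x) ifelse(x > 0, x, expm1(x)),
    grad = function(x) ifelse(x > 0, 1, exp(x))
  ),
  relu = list(
    f = function(x) pmax(x, 0),
    grad = function(x) as.numeric(x > 0)
  ),
  tanh = list(
    f = tanh,
    grad = function(x) 1 - tanh(x)^2
  ),
  identity = list(
    f = identity,
    grad = function(x) rep(1, length(x))
  )
)

get_activation <- function(name) {
  act <- .activations[[name]]
  if (is.null(act)) {
    stop("unknown activation '", name, "'; available: ",
         paste(names(.activations), collapse = ", "))
  }
  act
}

# Glorot/Xavier uniform initialisation for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# --- recursive tensor-tree utilities -----------------------------------------
# Model parameters are nested named lists whose leaves are numeric arrays.
# Gradients and Adam moments mirror that structure exactly.

tree_map <- function(f, tree, ...) {
  if (is.list(tree)) {
    extra <- list(...)
    out <- vector("list", length(tree))
    names(out) <- names(tree)
    for (k in seq_along(tree)) {
      out[[k]] <- do.call(tree_map, c(list(f, tree[[k]]), lapply(extra, `[[`, k)))
    }
    out
  } else {
    f(tree, ...)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(function(x, y) x + y, a, b)

tree_all_finite <- function(tree) {
  ok <- TRUE
  walk <- function(t) {
    if (is.list(t)) lapply(t, walk) else if (!all(is.finite(t))) ok <<- FALSE
    invisible(NULL)
  }
  walk(tree)
  ok
}

# --- Adam optimizer ----------------------------------------------------------

adam_init <- function(params, lr = 0.003, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zeros_like(params), v = tree_zeros_like(params))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - state$lr * (m / c1) / (sqrt(v / c2) + state$eps)
  }, params, state$m, state$v)
  list(state = state, params = params)
}
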