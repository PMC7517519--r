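# Internal numerical helpers shared across the network modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Deterministically mix a base seed with stream indices into a 32-bit seed.
# Multiplier/modulus are the classic Marsaglia LCG constants; exact doubles
# up to 2^53 keep the arithmetic portable.
derive_seed <- function(...) {
  vals <- as.numeric(c(...))
  x <- 0
  for (v in vals) {
    x <- (x * 69069 + (abs(v) %% 2147483647)) %% 2147483647
  }
  as.integer(x %% 2147483646 + 1)
}

# Glorot/Xavier uniform initialization.
xavier <- function(dim, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -limit, limit), dim = dim)
}

# Apply f(leaf_a, leaf_b, name) over two parallel nested lists of arrays,
# returning the transformed first argument. Used for L2 gradients.
param_map2 <- function(a, b, f, name = "") {
  if (is.list(a)) {
    for (nm in names(a)) {
      a[[nm]] <- param_map2(a[[nm]], b[[nm]], f, nm)
    }
    return(a)
  }
  f(a, b, name)
}

# Apply f(leaf, name) over a nested parameter list.
param_map <- function(a, f, name = "") {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- param_map(a[[nm]], f, nm)
    return(a)
  }
  f(a, name)
}

# Elementwise sum of two parallel nested parameter lists.
param_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- param_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

param_sq_norm <- function(a, weights_only = TRUE) {
  total <- 0
  walk <- function(x, name) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], nm)
    } else if (!weights_only || is_weight_name(name)) {
      total <<- total + sum(x^2)
    }
  }
  walk(a, "")
  total
}

# Leaves named W*, U* are multiplicative weights (penalized); b* are biases.
is_weight_name <- function(name) {
  substr(name, 1, 1) %in% c("W", "U")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
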