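# internal numeric helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# One Dirichlet draw. Guards the all-mass-lost case that rgamma() can hit
# when every concentration parameter is tiny.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0 || !is.finite(s)) {
    out <- numeric(length(alpha))
    out[sample.int(length(alpha), 1L, prob = alpha)] <- 1
    return(out)
  }
  g / s
}

rdirichlet <- function(n, alpha) {
  t(vapply(seq_len(n), function(i) rdirichlet1(alpha), numeric(length(alpha))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_field <- function(x, sep = ";") {
  strsplit(as.character(x), sep, fixed = TRUE)
}

join_field <- function(x, sep = ";") {
  vapply(x, paste, character(1), collapse = sep)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
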