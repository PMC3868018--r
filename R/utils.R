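# Internal numerical helpers.

# Clamp probabilities away from 0/1 before odds-ratio combinations and logs.
clamp_prob <- function(p, eps = 1e-9) {
  pmin(pmax(p, eps), 1 - eps)
}

# Numerically stable log(plogis(z)) = -log(1 + exp(-z)).
log_plogis <- function(z) {
  -log1p(exp(-abs(z))) + pmin(z, 0)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical color coding: "G"/"B". Accepts long names case-insensitively.
normalize_color <- function(x) {
  out <- toupper(as.character(x))
  out[out == "GREEN"] <- "G"
  out[out == "BLUE"] <- "B"
  bad <- !(out %in% c("G", "B"))
  if (any(bad)) {
    stop("invalid color code(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected 'G'/'B' or 'green'/'blue')", call. = FALSE)
  }
  out
}

other_color <- function(x) ifelse(x == "G", "B", "G")

assert_binary <- function(x, what = "outcomes") {
  if (length(x) == 0 || !is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(what, " must be a non-empty 0/1 sequence", call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive a stage seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919) %% 2147483647)
}

# Round all numeric leaves to 12 significant digits (result serialization).
signif12 <- function(x) {
  rapply(x, function(v) if (is.double(v)) signif(v, 12) else v,
         how = "replace")
}

write_json_result <- function(x, path) {
  jsonlite::write_json(signif12(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
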