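# input validation helpers; error messages name the offending field

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a positive finite number: got ",
         deparse(substitute(x, parent.frame())), " = ", format(x), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop("'", name, "' must be an integer >= ", min, ": got ", format(x),
         call. = FALSE)
  as.integer(x)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length axis vector", call. = FALSE)
  v / n
}

# stable short content hash (FNV-1a, 32 bit) for provenance stamps;
# arithmetic kept in doubles, multiply split to stay under 2^53
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste(sprintf("%02x", as.integer((h %/% c(16777216, 65536, 256, 1)) %% 256)),
        collapse = "")
}
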