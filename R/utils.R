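# internal helpers shared across modules

# Run `expr` under a given RNG seed, restoring the caller's RNG state on exit
# so that seeded package functions never disturb the global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits; stamps
# output files with a configuration fingerprint without a digest dependency.
# The multiplication is split into 16-bit halves so every intermediate stays
# exactly representable in a double.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  prime <- 16777619
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor_num(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# bitwXor for non-negative numbers that may exceed .Machine$integer.max
bitwXor_num <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

config_hash <- function(obj) {
  fnv1a(paste(deparse(obj), collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pupsurv <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pupsurv_error")))
}
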