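# Internal helpers shared across modules.

# Half-open interval membership [a, b); used everywhere a window is tested so
# that a single boundary convention holds for binning, phases and epochs.
in_window <- function(t, a, b) t >= a & t < b

# Deterministic sub-seed table: one master seed yields a fixed pool of
# component seeds, so adding units to a session never perturbs the streams of
# components that already existed (pressure = slot 1, LFP = slot 2, PMC unit i
# = slot 16 + i, LC unit j = slot 2064 + j).
SUBSEED_POOL <- 4096L

subseeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, SUBSEED_POOL)
}

subseed_slot <- function(component, index = 0L) {
  slot <- switch(component,
    pressure = 1L,
    lfp      = 2L,
    pmc      = 16L + as.integer(index),
    lc       = 2064L + as.integer(index),
    stop("unknown component: ", component)
  )
  if (slot > SUBSEED_POOL) stop("sub-seed pool exhausted for component ", component)
  slot
}

# FNV-1a hash over a character scalar; used for provenance fingerprints.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
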