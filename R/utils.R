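# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from one user-supplied seed.  Each
#' stage (and each subject within a stage) draws from its own substream whose
#' seed is a deterministic hash of `(seed, label, index)`, so regenerating any
#' single piece of the cohort reproduces it exactly without replaying the
#' whole stream.
#'
#' @param seed Integer master seed.
#' @param label Character stage label (e.g. `"bold"`, `"motion"`).
#' @param index Optional integer index within the stage (e.g. subject number).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, keeps everything in 32-bit integer range
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

# local seed scope: set RNG state, restore on exit
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable content checksum of an R object (used for determinism contracts
# and the run manifest); serialization version pinned for reproducibility
content_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 3L, xdr = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

# 0-based voxel index -> world (mm) coordinate through the affine
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "gfcmap_input_error")
stop_config <- function(msg, ...) abort(sprintf(msg, ...), class = "gfcmap_config_error")
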