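# internal helpers

# Fingerprint of a panel (ids plus a cheap content checksum); used to verify
# that a kernel and a backsolve refer to the same panel.
panelDigest <- function(lineIds, predictorIds, m = NULL) {
  chk <- if (is.null(m)) "" else
    sprintf("%.0f:%.6g", sum(m), sum(m * outer(seq_len(nrow(m)), seq_len(ncol(m)))))
  paste0(length(lineIds), "/", length(predictorIds), "|",
         paste(lineIds, collapse = "\r"), "||",
         paste(predictorIds, collapse = "\r"), "##", chk)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Symmetric PSD projection by eigenvalue clipping.
projectPSD <- function(A, clip = 1e-10) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  floorVal <- clip * sum(abs(diag(A)))
  if (all(e$values >= floorVal * 0)) {
    if (min(e$values) >= 0) return(A)
  }
  vals <- pmax(e$values, 0)
  B <- e$vectors %*% (vals * t(e$vectors))
  (B + t(B)) / 2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))
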