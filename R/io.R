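# Tabular writers and run manifests for the analysis pipeline.

#' Write a results table as CSV with fixed formatting
#'
#' Locale-independent decimal points, money columns to 2 decimals,
#' probability/effect columns to 6. Column order is preserved.
#'
#' @param rows Data.frame.
#' @param path Output path.
#' @param money_cols,prob_cols Character vectors of column names to format.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, money_cols = character(0),
                        prob_cols = character(0)) {
  stopifnot(is.data.frame(rows))
  missing <- setdiff(c(money_cols, prob_cols), names(rows))
  if (length(missing)) {
    stop("schema mismatch: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in money_cols) rows[[cl]] <- sprintf("%.2f", rows[[cl]])
  for (cl in prob_cols) rows[[cl]] <- sprintf("%.6f", rows[[cl]])
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 64-bit FNV-1a over a character scalar, reported as 16 hex digits.
# Arithmetic is done in two 32-bit halves to stay exact in doubles.
fnv1a64 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(text))
  lo <- 0x84222325
  hi <- 0xcbf29ce4
  p_lo <- 0x1b3
  p_hi <- 0x100
  for (b in bytes) {
    lo <- bitwXor32(lo, b)
    # (hi,lo) * (p_hi,p_lo) mod 2^64, via 16-bit limbs
    a0 <- lo %% 65536; a1 <- lo %/% 65536
    a2 <- hi %% 65536; a3 <- hi %/% 65536
    b0 <- p_lo %% 65536; b1 <- p_lo %/% 65536
    b2 <- p_hi %% 65536
    c0 <- a0 * b0
    c1 <- a1 * b0 + a0 * b1 + c0 %/% 65536
    c2 <- a2 * b0 + a1 * b1 + a0 * b2 + c1 %/% 65536
    c3 <- a3 * b0 + a2 * b1 + a1 * b2 + c2 %/% 65536
    lo <- (c0 %% 65536) + (c1 %% 65536) * 65536
    hi <- (c2 %% 65536) + (c3 %% 65536) * 65536
  }
  # values may exceed the signed 32-bit range, so format in 16-bit halves
  hex32 <- function(x) sprintf("%04x%04x", as.integer(x %/% 65536),
                               as.integer(x %% 65536))
  paste0(hex32(hi), hex32(lo))
}

bitwXor32 <- function(x, y) {
  # bitwXor works on 32-bit signed ints; keep values in [0, 2^32)
  r <- bitwXor(as.integer(x %% 2^31), as.integer(y))
  if (x >= 2^31) r <- r + 2^31
  r
}

#' Stable digest of a parameter set
#'
#' Platform-independent hash of the parameter ids and their values at full
#' precision; identical parameter sets give identical digests.
#'
#' @param params A `cea_params`.
#' @return 16-character hex string.
#' @export
parameter_digest <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  text <- paste(names(params$values),
                sprintf("%.17g", params$values),
                sep = "=", collapse = ";")
  fnv1a64(text)
}

#' Run manifest for a pipeline stage
#'
#' Records what was run, with which parameters (by digest) and seeds, and
#' which files were written; re-running with the same digest and seeds
#' reproduces the outputs bit-for-bit.
#'
#' @param command Stage name.
#' @param params A `cea_params`.
#' @param seed Integer seed(s) used (or `NULL`).
#' @param outputs Character vector of output file paths.
#' @param path Optional JSON path to write the manifest to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(command, params, seed = NULL,
                         outputs = character(0), path = NULL) {
  manifest <- list(
    command = command,
    parameter_digest = parameter_digest(params),
    seed = seed,
    package_version = as.character(utils::packageVersion("deafscreenCEA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    return(invisible(manifest))
  }
  manifest
}
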