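# internal helpers shared across modules

#' Derive a deterministic child seed for a pipeline stage
#'
#' All randomness in the package flows from one master seed; each stage
#' draws from its own child seed so that adding a stage never perturbs the
#' streams of the others.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.double(master)) * 48271 + h * 9973 + 12345) %% 2147483587)
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table with a header line
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_msg("input file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a table as TSV with a header line and stable column order
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# matrix (transcripts x samples) <-> TSV with a leading transcript_id column
write_matrix_tsv <- function(m, path, id_col = "transcript_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_file(df, path)
}

# Poisson draws that stay finite for very large rates (normal approximation
# above 1e7, where the two are indistinguishable)
safe_rpois <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e7
  out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big))
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  out
}

read_matrix_tsv <- function(path, id_col = "transcript_id") {
  df <- read_tsv_file(path)
  if (names(df)[1] != id_col)
    stop_msg("expected first column '%s' in %s, found '%s'",
             id_col, path, names(df)[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
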