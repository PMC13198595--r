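# small internal utilities

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded components never perturb the global
#' random stream. With \code{seed = NULL} the expression runs on the
#' current stream.
#'
#' @param seed Integer seed or NULL.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of a serialized R object via a temp file (tools::md5sum is file-based)
.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

# write a TSV with a provenance header comment
.write_run_table <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vhpotools %s%s", as.character(packageVersion("vhpotools")),
                     if (is.null(config_hash)) "" else paste0(" config=", config_hash)),
             con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

# read a TSV written by .write_run_table (or any plain TSV)
read_tsv_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
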