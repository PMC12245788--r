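# internal helpers: logging, dialect detection, validation patterns

# PDB entry: one digit then three alphanumerics (e.g. 1ABC)
.re_pdb <- "^[0-9][A-Za-z0-9]{3}$"
# UniProt accession: 6 or 10 alphanumerics starting with a letter
.re_uniprot <- "^[A-Za-z][A-Za-z0-9]{5}([A-Za-z0-9]{4})?$"

#' @keywords internal
#' @noRd
dfp_log <- function(fmt, ..., level = "INFO") {
  if (isTRUE(getOption("dockfp.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %-5s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level,
                  sprintf(fmt, ...)))
  invisible(NULL)
}

# delimiter by extension: tab for .tsv/.tab, comma otherwise; sep overrides
.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

.read_table <- function(path, sep = NULL) {
  utils::read.table(path, header = TRUE, sep = .detect_sep(path, sep),
                    quote = "\"", comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    strip.white = TRUE)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

# suppress scientific notation so tabular output is stable and readable
.num_chr <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}
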