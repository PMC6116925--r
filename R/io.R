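# FASTA input, seeded fixture generation, and matrix/dot-plot export.

#' Read RNA sequences from a FASTA file
#'
#' Records are normalized like every other sequence input (uppercase,
#' `T -> U`); illegal residues are reported with their record and position.
#'
#' @param path path to a FASTA file.
#' @return Named list of [rna_seq()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input("malformed FASTA: %s",
                                                 conditionMessage(e)))
  if (length(set) == 0) stop_input("FASTA file contains no record: %s", path)
  out <- lapply(seq_along(set), function(k) {
    tryCatch(rna_seq(as.character(set[[k]])),
             rnakit_input_error = function(e)
               stop_input("record %d (%s): %s", k, names(set)[k],
                          conditionMessage(e)))
  })
  names(out) <- names(set)
  out
}

#' Deterministic fixture sequences
#'
#' Generates `count` random RNA sequences (lengths uniform over
#' `length_range`, GC content controlled by `gc_bias`) under a fixed seed —
#' identical arguments give byte-identical output — and appends the
#' canonical teaching inputs as named entries: `"single-pair"` (GAAAC),
#' `"hairpin"` (GGGAAACCC) and `"demo-interaction"` (the CCC / CCCGGGGGG
#' duplex).  The caller's RNG state is left untouched.
#'
#' @param count number of random sequences.
#' @param length_range integer range `c(min, max)` of sequence lengths.
#' @param gc_bias probability mass on `{G, C}` (0.5 = uniform over the four
#'   bases; 1 = G/C only).
#' @param seed RNG seed.
#' @return Named list of character sequences (`random-001`, ..., plus the
#'   canonical entries; `"demo-interaction"` is a length-2 vector).
#' @export
generate_fixtures <- function(count = 50, length_range = c(5, 12),
                              gc_bias = 0.5, seed = 1) {
  if (gc_bias < 0 || gc_bias > 1) stop_input("gc_bias must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
             G = gc_bias / 2, U = (1 - gc_bias) / 2)
  lens <- sample(length_range[1]:length_range[2], count, replace = TRUE)
  rand <- lapply(lens, function(n)
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = ""))
  names(rand) <- sprintf("random-%03d", seq_len(count))
  c(rand,
    list("single-pair" = "GAAAC",
         "hairpin" = "GGGAAACCC",
         "demo-interaction" = c("CCC", "CCCGGGGGG")))
}

#' Export a matrix as TSV or JSON
#'
#' Renders any of the package's tables (counting, score, partition, MEA,
#' hybridization) as a document string: TSV with 1-based `i`/`j` headers, or
#' JSON nested lists.  Counting matrices should be passed as their `exact`
#' character component so arbitrary-precision values survive untouched.
#'
#' @param table a matrix (numeric or character).
#' @param dialect `"tsv"` or `"json"`.
#' @param digits decimal places for numeric TSV output (default 6).
#' @return A single character string.
#' @export
export_matrix <- function(table, dialect = c("tsv", "json"), digits = 6) {
  dialect <- match.arg(dialect)
  if (inherits(table, "count_matrix")) table <- table$exact
  if (!is.matrix(table)) stop_input("export_matrix expects a matrix")
  if (dialect == "json")
    return(as.character(jsonlite::toJSON(table, digits = NA, na = "null")))
  fmt <- function(v) {
    if (is.character(v)) ifelse(is.na(v), "", v)
    else ifelse(is.na(v), "", formatC(v, format = "f", digits = digits))
  }
  rows <- vapply(seq_len(nrow(table)), function(i)
    paste(c(i, fmt(table[i, ])), collapse = "\t"), "")
  paste(c(paste(c("i\\j", seq_len(ncol(table))), collapse = "\t"), rows),
        collapse = "\n")
}

#' Serialize a dot-plot
#'
#' TSV dialect: a `i  j  probability` table for the base-pair records
#' followed by a `k  pr_u` block; JSON dialect mirrors both data frames.
#'
#' @param x an [dotplot()] result.
#' @param dialect `"tsv"` or `"json"`.
#' @param digits decimal places in TSV mode.
#' @return A single character string.
#' @export
format_dotplot <- function(x, dialect = c("tsv", "json"), digits = 6) {
  dialect <- match.arg(dialect)
  if (dialect == "json")
    return(as.character(jsonlite::toJSON(
      list(basepairs = x$bp, unpaired = x$unpaired), digits = NA,
      dataframe = "rows")))
  f <- function(v) formatC(v, format = "f", digits = digits)
  lines <- c("i\tj\tprobability",
             sprintf("%d\t%d\t%s", x$bp$i, x$bp$j, f(x$bp$prob)),
             "",
             "k\tpr_u",
             sprintf("%d\t%s", x$unpaired$k, f(x$unpaired$pr_u)))
  paste(lines, collapse = "\n")
}
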