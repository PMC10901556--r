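GAP_CHARS <- c("-", "X", "?", ".", "*")

#' Coerce sequences to an amino-acid alignment
#'
#' The package-internal alignment form is a character matrix (rows = taxa,
#' columns = alignment sites, uppercase one-letter residues, `-` for gaps and
#' `X` for ambiguity) with class `aa_alignment`. Accepted inputs: a named
#' character vector of equal-length strings, a character matrix with
#' rownames, an `ape::AAbin`, or a `phangorn::phyDat` of type AA.
#'
#' @param x Sequences in any accepted form.
#' @return An `aa_alignment` character matrix.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "aa_alignment")) return(x)
  if (inherits(x, "phyDat")) x <- as.character(x)
  if (inherits(x, "AAbin")) x <- as.character(as.matrix(x))
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) abort("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1) abort("all sequences must have equal length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) {
    abort("cannot interpret input as an alignment")
  }
  if (is.null(rownames(x))) abort("alignment rows must be labelled")
  if (anyDuplicated(rownames(x))) abort("duplicate sequence labels")
  m <- toupper(x)
  m[m %in% c("?", ".", "*")] <- "X"
  bad <- setdiff(unique(as.vector(m)), c(AA_ALPHABET, "-", "X"))
  if (length(bad) > 0) {
    abort(paste0("unknown residue code(s): ", paste(bad, collapse = " ")))
  }
  structure(m, class = c("aa_alignment", class(m)))
}

#' Read a protein alignment from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file of aligned amino-acid
#'   sequences.
#' @return An `aa_alignment` matrix.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path, type = "AA")
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    abort("FASTA sequences have unequal lengths; not an alignment")
  }
  as_alignment(seqs)
}

#' Write sequences to FASTA
#'
#' @param x An alignment or named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.matrix(x)) x <- apply(x, 1, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(x)), unname(x)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", nrow(x), " sequences x ", ncol(x), " sites\n",
      sep = "")
  show <- utils::head(rownames(x), 5)
  for (s in show) {
    cat(sprintf("  %-20s %s\n", s,
                paste(utils::head(x[s, ], 40), collapse = "")))
  }
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

# Integer state matrix: 1..20 residues, NA for gap/ambiguity.
alignment_states <- function(aln) {
  m <- as_alignment(aln)
  s <- match(m, AA_ALPHABET)
  dim(s) <- dim(m)
  rownames(s) <- rownames(m)
  s
}
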