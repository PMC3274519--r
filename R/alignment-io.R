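#' @importFrom stats setNames optim optimize rexp rpois runif rmultinom
#' @importFrom utils read.delim write.table combn
NULL

VALID_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
# IUPAC ambiguity codes (plus gap and N) tolerated on input, never counted as
# distinct states
IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-", "?")

#' Construct a validated alignment object
#'
#' An alignment is a set of equal-length nucleotide sequences with unique
#' sample identifiers, the raw input of every downstream stage.  Sequences are
#' upper-cased on construction; characters outside the IUPAC nucleotide
#' alphabet (plus \code{-} and \code{?}) are rejected.
#'
#' @param seqs named character vector of nucleotide strings.
#' @return object of class \code{mp_alignment} with elements \code{seq}
#'   (named uppercase character vector), \code{ids} and \code{L} (alignment
#'   length in sites).
#' @export
alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment is empty")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named with sample ids")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  L <- lens[[1L]]
  if (any(lens != L)) {
    bad <- ids[lens != L]
    stop("ragged alignment: sequences with deviant length: ",
         paste(bad, collapse = ", "))
  }
  alphabet <- c(VALID_BASES, IUPAC_EXTRA)
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  bad_chars <- setdiff(chars, alphabet)
  if (length(bad_chars))
    stop("invalid characters in alignment: ", paste(bad_chars, collapse = ", "))
  structure(list(seq = setNames(as.character(seqs), ids), ids = ids, L = L),
            class = "mp_alignment")
}

#' @export
print.mp_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$L, "sites\n")
  invisible(x)
}

#' @export
as.matrix.mp_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seq, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Subset an alignment by sample id
#' @param aln an \code{mp_alignment}.
#' @param ids sample ids to keep (order preserved).
#' @return the restricted \code{mp_alignment}.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  alignment(aln$seq[ids])
}

#' Read an aligned FASTA plus a sample-to-population map
#'
#' The population map is a tab-separated file with header
#' \code{sample_id<TAB>population_id<TAB>group_id}.  Every FASTA record must
#' be mapped; unmapped samples, ragged alignments and empty files are hard
#' errors.  Mixed-case sequence is normalised to upper case.
#'
#' @param fasta_path path to a multi-record FASTA (wrapped or unwrapped).
#' @param popmap_path path to the population-map TSV.
#' @return list with \code{alignment} (\code{mp_alignment}) and
#'   \code{popmap} (data.frame sample_id / population_id / group_id).
#' @export
read_alignment <- function(fasta_path, popmap_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(popmap_path)) stop("population map not found: ", popmap_path)
  dna <- suppressWarnings(ape::read.FASTA(fasta_path))
  if (is.null(dna) || length(dna) == 0L) stop("empty FASTA: ", fasta_path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  names(seqs) <- names(dna)
  aln <- alignment(seqs)
  pm <- read_popmap(popmap_path)
  check_popmap(aln, pm)
  list(alignment = aln, popmap = pm)
}

#' Read a population map TSV
#' @param path TSV with columns sample_id, population_id, group_id.
#' @return data.frame with character columns.
#' @export
read_popmap <- function(path) {
  pm <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "population_id", "group_id")
  if (!all(need %in% names(pm)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  pm <- pm[, need]
  if (anyDuplicated(pm$sample_id))
    stop("duplicate sample ids in population map")
  # a population must sit in exactly one group
  gp <- unique(pm[, c("population_id", "group_id")])
  if (anyDuplicated(gp$population_id))
    stop("population assigned to more than one group: ",
         paste(gp$population_id[duplicated(gp$population_id)], collapse = ", "))
  pm
}

check_popmap <- function(aln, pm) {
  unmapped <- setdiff(aln$ids, pm$sample_id)
  if (length(unmapped))
    stop("samples missing from population map: ", paste(unmapped, collapse = ", "))
  invisible(TRUE)
}

#' Collapse an alignment into haplotypes with per-population counts
#'
#' Haplotype identity is exact string equality over all sites after case
#' normalisation (sequences containing N or other ambiguity collapse only
#' with exact matches).  Haplotype ids \code{H1, H2, ...} are assigned in
#' order of first appearance, making the result deterministic.
#'
#' @param aln an \code{mp_alignment}.
#' @param popmap population map data.frame (or NULL for a single pseudo
#'   population "all").
#' @return object of class \code{mp_haplotypes}: \code{seq} named character
#'   vector of distinct haplotype sequences, \code{counts} matrix (haplotype
#'   x population), \code{assignment} named vector sample_id -> haplotype_id,
#'   and \code{L}.
#' @export
collapse_haplotypes <- function(aln, popmap = NULL) {
  if (is.null(popmap)) {
    popmap <- data.frame(sample_id = aln$ids, population_id = "all",
                         group_id = "all", stringsAsFactors = FALSE)
  }
  check_popmap(aln, popmap)
  uniq <- unique(unname(aln$seq))
  hap_id <- paste0("H", seq_along(uniq))
  idx <- match(aln$seq, uniq)
  assignment <- setNames(hap_id[idx], aln$ids)
  pops <- unique(popmap$population_id)
  pop_of <- setNames(popmap$population_id, popmap$sample_id)[aln$ids]
  counts <- table(factor(hap_id[idx], levels = hap_id),
                  factor(pop_of, levels = pops))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(hap_id, pops))
  structure(list(seq = setNames(uniq, hap_id), counts = counts,
                 assignment = assignment, L = aln$L),
            class = "mp_haplotypes")
}

#' @export
print.mp_haplotypes <- function(x, ...) {
  cat("HaplotypeTable:", length(x$seq), "haplotypes,",
      sum(x$counts), "samples,", ncol(x$counts), "populations\n")
  invisible(x)
}

#' Expand a haplotype table back to per-sample sequences
#' @param haps an \code{mp_haplotypes}.
#' @return named character vector, one entry per sample (ids synthesised from
#'   haplotype and population when the original assignment is absent).
#' @export
expand_haplotypes <- function(haps) {
  if (!is.null(haps$assignment)) {
    return(setNames(unname(haps$seq[haps$assignment]), names(haps$assignment)))
  }
  out <- character(0)
  for (h in rownames(haps$counts)) {
    for (p in colnames(haps$counts)) {
      k <- haps$counts[h, p]
      if (k > 0)
        out <- c(out, setNames(rep(haps$seq[[h]], k),
                               paste(h, p, seq_len(k), sep = "_")))
    }
  }
  out
}

#' Write an alignment as FASTA
#' @param aln an \code{mp_alignment}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$ids) {
    writeLines(c(paste0(">", id), aln$seq[[id]]), con)
  }
  invisible(path)
}
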