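#' Aligned DNA sequences
#'
#' A thin container for a multiple-sequence alignment: a character matrix of
#' single upper-case symbols (rows = sequences, unique row names = labels),
#' all rows the same length. Accepted symbols are the four bases, IUPAC
#' ambiguity codes, `N`, `-` and `?`.
#'
#' @param x character matrix of single characters, or a named character vector
#'   of sequence strings of equal length.
#' @return A `dna_alignment` (character matrix).
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequence vector must be named")
    n <- unique(nchar(x))
    if (length(n) != 1L) stop("sequences have unequal lengths")
    x <- matrix(unlist(strsplit(toupper(x), "")), nrow = length(x),
                byrow = TRUE, dimnames = list(names(x), NULL))
  }
  if (!is.matrix(x) || !is.character(x)) stop("need a character matrix")
  if (nrow(x) == 0L) stop("empty alignment")
  x[] <- toupper(x)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("rows must carry unique labels")
  allowed <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
  bad <- setdiff(unique(as.vector(x)), allowed)
  if (length(bad)) stop("invalid symbols in alignment: ",
                        paste(bad, collapse = " "))
  structure(x, class = c("dna_alignment", class(x)))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path file path.
#' @return A [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) stop("FASTA sequences are not aligned")
  m <- toupper(as.character(as.matrix(dna)))
  dna_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Collapse aligned sequences to unique haplotypes
#'
#' Two records share a haplotype when their sequences are identical site by
#' site. With `ignore_missing = TRUE`, sites where either record has `-`, `?`
#' or `N` are skipped in the comparison and records are grouped by the
#' transitive closure of that (reflexive, symmetric) compatibility relation,
#' the common alternative collapsing rule when sequences have ragged ends.
#'
#' @param aln a [dna_alignment()].
#' @param ignore_missing logical; see Details.
#' @return An object of class `haplotype_set`: list with `haplotypes`
#'   (character vector of representative sequences), `members` (list of label
#'   vectors per haplotype), `counts`, and `assignment` (named integer vector
#'   label -> haplotype index).
#' @export
collapse_haplotypes <- function(aln, ignore_missing = FALSE) {
  if (!inherits(aln, "dna_alignment")) aln <- dna_alignment(aln)
  n <- nrow(aln)
  labels <- rownames(aln)
  if (!ignore_missing) {
    seqs <- apply(aln, 1, paste, collapse = "")
    grp <- match(seqs, unique(seqs))
  } else {
    # union-find over pairwise compatibility
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    miss <- aln %in% c("-", "?", "N")
    dim(miss) <- dim(aln)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !(miss[i, ] | miss[j, ])
      if (all(aln[i, ok] == aln[j, ok])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    grp <- match(roots, unique(roots))
  }
  members <- split(labels, grp)
  reps <- vapply(split(seq_len(n), grp), function(ix)
    paste(aln[ix[1], ], collapse = ""), character(1))
  structure(list(haplotypes = unname(reps),
                 members = unname(members),
                 counts = unname(lengths(members)),
                 assignment = setNames(grp, labels)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sum(x$counts), "sequences collapsed to", length(x$haplotypes),
      "haplotypes\n")
  invisible(x)
}

#' Write a haplotype mapping table
#'
#' @param hs a `haplotype_set`.
#' @param path output path (tab-separated: label, haplotype id).
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(hs, path) {
  df <- data.frame(label = names(hs$assignment),
                   haplotype = paste0("hap", hs$assignment))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reading-frame quality check for protein-coding alignments
#'
#' Translates each record in the given frame and reports internal stop codons
#' and non-translatable codons (codons containing gaps or ambiguity symbols).
#' The terminal codon is allowed to be a stop. Default code is the vertebrate
#' mitochondrial one (appropriate for cytochrome b and other mtDNA markers).
#'
#' @param aln a [dna_alignment()].
#' @param code NCBI genetic code id as a string (default `"2"`, vertebrate
#'   mitochondrial; `"1"` = standard).
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return data.frame with one row per violation: `label`, `codon_index`
#'   (1-based, in the translated frame), `site` (first alignment column of the
#'   codon), `codon`, `type` (`"stop"` or `"untranslatable"`).
#' @export
check_coding <- function(aln, code = "2", frame = 0L) {
  if (!inherits(aln, "dna_alignment")) aln <- dna_alignment(aln)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  tab <- Biostrings::getGeneticCode(code)
  out <- list()
  for (i in seq_len(nrow(aln))) {
    s <- aln[i, ]
    s <- s[(frame + 1L):length(s)]
    n_codon <- length(s) %/% 3L
    if (n_codon < 1L) next
    idx <- 3L * (seq_len(n_codon) - 1L)
    codons <- paste0(s[idx + 1L], s[idx + 2L], s[idx + 3L])
    known <- codons %in% names(tab)
    aa <- rep(NA_character_, n_codon)
    aa[known] <- unname(tab[codons[known]])
    internal <- seq_len(n_codon) < n_codon
    bad_stop <- which(!is.na(aa) & aa == "*" & internal)
    bad_untr <- which(!known)
    for (b in bad_stop)
      out[[length(out) + 1L]] <- data.frame(
        label = rownames(aln)[i], codon_index = b,
        site = frame + 3L * (b - 1L) + 1L, codon = codons[b], type = "stop")
    for (b in bad_untr)
      out[[length(out) + 1L]] <- data.frame(
        label = rownames(aln)[i], codon_index = b,
        site = frame + 3L * (b - 1L) + 1L, codon = codons[b],
        type = "untranslatable")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(label = character(), codon_index = integer(),
               site = integer(), codon = character(), type = character())
}
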