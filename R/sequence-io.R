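#' Read coding sequences from FASTA or GenBank
#'
#' Loads one CDS per FASTA record, or extracts every CDS feature from a
#' GenBank flat file (honouring `join()` and `complement()` locations; the
#' gene name comes from the `/gene` qualifier, falling back to `/product`).
#' Sequences are upper-cased and U is normalised to T. A record whose length
#' is not a multiple of 3, or that contains a character outside A/C/G/T/U,
#' raises an error naming the record.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"genbank"`.
#' @param strain_id Label recorded in the `strain` column for every record.
#'
#' @return A tibble with columns `strain`, `gene`, `seq`, `length_nt`, in
#'   order of appearance in the file.
#' @seealso [filter_core_genes()], [write_cds()]
#' @export
read_cds <- function(path, format = c("fasta", "genbank"), strain_id) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read CDS file: ", path, call. = FALSE)
  }
  recs <- switch(format,
    fasta = read_cds_fasta(path),
    genbank = read_genbank_cds(path)
  )
  seqs <- vapply(seq_len(nrow(recs)), function(i) {
    validate_cds_seq(recs$seq[[i]], recs$gene[[i]])
  }, character(1))
  tibble::tibble(
    strain = strain_id,
    gene = recs$gene,
    seq = seqs,
    length_nt = nchar(seqs)
  )
}

read_cds_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(
    # first whitespace-delimited token of the header is the gene name
    gene = vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L),
    seq = as.character(x)
  )
}

validate_cds_seq <- function(seq, record) {
  s <- chartr("U", "T", toupper(seq))
  bad <- regmatches(s, regexpr("[^ACGT]", s))
  if (length(bad) > 0) {
    stop(sprintf("record '%s': invalid character '%s' (alphabet is A/C/G/T/U)",
                 record, bad), call. = FALSE)
  }
  if (nchar(s) %% 3L != 0L) {
    stop(sprintf("record '%s': length %d is not a multiple of 3",
                 record, nchar(s)), call. = FALSE)
  }
  s
}

# ---- GenBank flat-file CDS extraction -------------------------------------
#
# Minimal feature-table parser: enough for CDS features with plain,
# join(...) and complement(...) locations (complement may wrap join).
# Coordinates are GenBank 1-based inclusive. complement(join(a..b, c..d))
# means reverse-complement of the concatenated segments.

read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ori <- grep("^ORIGIN", lines)
  end <- grep("^//", lines)
  if (length(ori) == 0) stop("GenBank file has no ORIGIN section: ", path,
                             call. = FALSE)
  ori <- ori[1L]
  end <- if (length(end)) end[end > ori][1L] else length(lines) + 1L
  genome <- toupper(gsub("[^A-Za-z]", "", paste(lines[(ori + 1L):(end - 1L)],
                                                collapse = "")))

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) stop("GenBank file has no FEATURES table: ",
                                    path, call. = FALSE)
  feat <- lines[(feat_start[1L] + 1L):(ori - 1L)]

  # a feature header line has the key at column 6; continuations start deeper
  is_header <- grepl("^ {5}\\S", feat)
  idx <- which(is_header)
  genes <- character(0)
  seqs <- character(0)
  for (k in seq_along(idx)) {
    key <- sub("^ {5}(\\S+).*", "\\1", feat[idx[k]])
    if (key != "CDS") next
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(feat)
    block <- feat[idx[k]:to]
    # location: text after the key plus continuation lines before the first /
    body <- sub("^ {5}\\S+\\s*", "", block[1L])
    i <- 2L
    while (i <= length(block) && !grepl("^\\s*/", block[i])) {
      body <- paste0(body, trimws(block[i]))
      i <- i + 1L
    }
    loc <- gsub("\\s", "", body)
    quals <- block[grepl("^\\s*/", block)]
    gene <- genbank_qualifier(quals, "gene")
    if (is.na(gene)) gene <- genbank_qualifier(quals, "product")
    if (is.na(gene)) gene <- sprintf("CDS_%d", length(genes) + 1L)
    genes <- c(genes, gene)
    seqs <- c(seqs, extract_genbank_location(genome, loc))
  }
  tibble::tibble(gene = genes, seq = seqs)
}

genbank_qualifier <- function(quals, name) {
  pat <- paste0("^\\s*/", name, "=\"?([^\"]*)\"?\\s*$")
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(pat, "\\1", hit[1L])
}

extract_genbank_location <- function(genome, loc) {
  revcomp <- FALSE
  if (grepl("^complement\\(", loc)) {
    revcomp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",")[[1L]]
  segs <- vapply(parts, function(p) {
    rc <- grepl("^complement\\(", p)
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    p <- gsub("[<>]", "", p)
    rng <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (anyNA(rng)) stop("cannot parse GenBank location segment: ", p,
                         call. = FALSE)
    if (length(rng) == 1L) rng <- c(rng, rng)
    s <- substr(genome, rng[1L], rng[2L])
    if (rc) s <- revcomp_dna(s) else s
  }, character(1), USE.NAMES = FALSE)
  out <- paste(segs, collapse = "")
  if (revcomp) revcomp_dna(out) else out
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write coding sequences to a multi-record FASTA file
#'
#' The inverse of [read_cds()] for FASTA: headers are the gene names (one
#' strain per file), sequences unwrapped. Re-reading reproduces the
#' sequences byte-identically.
#'
#' @param seqs Tibble with `gene` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$gene
  Biostrings::writeXStringSet(x, path, width = 20001L)
  invisible(path)
}

#' Filter to core genes by length and name
#'
#' Retains sequences at least `min_len` nucleotides long (the conventional
#' 300 bp cut-off that removes fragmentary organellar ORFs) and, when a
#' whitelist is given, whose gene name matches it. Matching is
#' case-insensitive with a small alias map covering common GenBank qualifier
#' spellings (e.g. `cytb` for `cob`, `nad4L` vs `nad4l`). Input order is
#' preserved and the operation is idempotent.
#'
#' @param seqs Tibble from [read_cds()] (columns `gene`, `seq`, and
#'   optionally `length_nt`).
#' @param min_len Minimum length in nucleotides (default 300).
#' @param gene_whitelist Optional character vector of gene names to keep.
#' @return The filtered tibble; a warning is raised if nothing survives.
#' @export
filter_core_genes <- function(seqs, min_len = 300, gene_whitelist = NULL) {
  len <- if ("length_nt" %in% names(seqs)) seqs$length_nt else nchar(seqs$seq)
  keep <- len >= min_len
  if (!is.null(gene_whitelist)) {
    keep <- keep &
      normalize_gene_name(seqs$gene) %in% normalize_gene_name(gene_whitelist)
  }
  out <- seqs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("filter_core_genes: no sequences retained", call. = FALSE)
  }
  out
}

# GenBank qualifier spellings vary; map to one canonical lower-case name.
GENE_ALIASES <- c(
  cytb = "cob", cob = "cob", "cyt-b" = "cob",
  coi = "cox1", coii = "cox2", coiii = "cox3",
  co1 = "cox1", co2 = "cox2", co3 = "cox3",
  atpase6 = "atp6", nd1 = "nad1", nd2 = "nad2", nd3 = "nad3",
  nd4 = "nad4", nd4l = "nad4l", nd5 = "nad5", nd6 = "nad6"
)

normalize_gene_name <- function(x) {
  lx <- tolower(trimws(x))
  hit <- match(lx, names(GENE_ALIASES))
  ifelse(is.na(hit), lx, unname(GENE_ALIASES[hit]))
}

#' Translate coding sequences
#'
#' Codon-by-codon translation under the chosen genetic code, vectorised over
#' sequences. A terminal stop codon is removed when `drop_terminal_stop` is
#' `TRUE`; internal stops are kept as `"*"` and reported with a warning.
#'
#' @param seq Character vector of validated CDS strings (length a multiple
#'   of 3, alphabet A/C/G/T).
#' @param code A [genetic_code()] object.
#' @param drop_terminal_stop Remove the final stop codon (default `TRUE`).
#' @return Character vector of amino-acid strings.
#' @examples
#' translate_cds("ATGTGGTAA")                      # "MW"
#' translate_cds("ATGTGA", genetic_code(4))        # "MW": TGA = Trp, table 4
#' @export
translate_cds <- function(seq, code = genetic_code(),
                          drop_terminal_stop = TRUE) {
  assert_genetic_code(code)
  out <- vapply(seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    starts <- seq.int(1L, n, 3L)
    aa <- unname(code$codon_to_aa[substring(s, starts, starts + 2L)])
    if (anyNA(aa)) stop("sequence contains an invalid codon", call. = FALSE)
    if (drop_terminal_stop && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    if (any(aa == "*")) {
      warning(sprintf("internal stop codon(s) at residue position(s) %s",
                      paste(which(aa == "*"), collapse = ", ")),
              call. = FALSE)
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(out == "")) {
    warning("empty translation (sequence was a lone stop codon or empty)",
            call. = FALSE)
  }
  out
}
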