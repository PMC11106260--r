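# Shared k-mer and small-sequence utilities. All heavy lifting is plain
# vectorized character work: at desk scale (megabase genomes) this is fast and
# keeps the whole toolkit dependency-light.

#' Reverse-complement character sequences
#'
#' Vectorized reverse complement for plain character DNA (IUPAC-aware).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGTRYKMBVDHacgtrykmbvdh",
                               "TGCAYRMKVBHDtgcayrmkvbhd", x))
}

#' Enumerate the k-mers of a sequence
#'
#' @param seq a single character sequence (or anything coercible via
#'   `as.character()`, e.g. a `DNAString`).
#' @param k k-mer size.
#' @return character vector of `nchar(seq) - k + 1` k-mers (empty if shorter).
#' @export
kmers_chr <- function(seq, k) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographic minimum of itself and its reverse
#' complement, so counting is strand-agnostic.
#'
#' @param x character vector of k-mers.
#' @return character vector, same length.
#' @export
canonical_kmers <- function(x) {
  pmin(x, revcomp_chr(x))
}

# k-mer -> multiplicity data.table over a set of sequences
.kmer_counts <- function(seqs, k, canonical = TRUE) {
  km <- unlist(lapply(as.character(seqs), kmers_chr, k = k), use.names = FALSE)
  if (canonical && length(km)) km <- canonical_kmers(km)
  dt <- data.table::data.table(kmer = km)
  if (nrow(dt) == 0L) return(data.table::data.table(kmer = character(0), n = integer(0)))
  dt[, list(n = .N), by = "kmer"]
}

# k-mer positions (1-based start) within one sequence, forward strand
.kmer_positions <- function(seq, k) {
  km <- kmers_chr(seq, k)
  data.table::data.table(kmer = km, pos = seq_along(km))
}

# fraction of a read's canonical k-mers found in a canonical reference set
.kmer_fraction_in_set <- function(reads_chr, kmer_set, k) {
  vapply(reads_chr, function(s) {
    km <- kmers_chr(s, k)
    if (!length(km)) return(0)
    mean(canonical_kmers(km) %chin% kmer_set)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read-length N50
#'
#' @param widths integer vector of sequence lengths.
#' @return the N50 length: the largest L such that sequences of length >= L
#'   hold at least half the total bases.
#' @export
n50 <- function(widths) {
  w <- sort(as.numeric(widths), decreasing = TRUE)
  if (!length(w)) return(NA_real_)
  w[which(cumsum(w) >= sum(w) / 2)[1]]
}

# random i.i.d. uniform ACGT sequence (uses the current RNG stream)
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at given 1-based positions with a uniformly chosen
# different base; operates on raw bytes for speed
.substitute_at <- function(seq, pos) {
  if (!length(pos)) return(seq)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  cur <- r[pos]
  new <- vapply(cur, function(b) sample(bases[bases != b], 1L), raw(1))
  r[pos] <- new
  rawToChar(r)
}

# per-base Bernoulli substitutions at rate p
.mutate_seq <- function(seq, p) {
  n <- nchar(seq)
  if (p <= 0 || n == 0L) return(seq)
  pos <- which(stats::runif(n) < p)
  .substitute_at(seq, pos)
}

# parse/format "key=value;key=value" attribute strings used in truth tables
.format_attrs <- function(...) {
  kv <- c(...)
  if (!length(kv)) return("")
  paste(paste0(names(kv), "=", kv), collapse = ";")
}

#' Parse a truth/call attribute string
#'
#' @param attrs a `key=value;key=value` string.
#' @return named character vector.
#' @export
parse_attrs <- function(attrs) {
  if (is.na(attrs) || !nzchar(attrs)) return(character(0))
  parts <- strsplit(attrs, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1L))
}

#' @importFrom data.table %chin% :=
#' @importFrom rlang .data
NULL
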