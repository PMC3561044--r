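## Codon-specific tRNA-capture rates from tRNA gene-copy numbers.
##
## tRNA abundances are taken proportional to gene copy numbers; the capture
## rate of a codon sums contributions of every anticodon that decodes it,
## weighted by a wobble-pairing efficiency factor at the third position.

RNA_BASES <- c("A", "C", "G", "U")

.wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

.codon_aa <- function(codons) {
  unname(Biostrings::RNA_GENETIC_CODE[codons])
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (RNA alphabet).
#' @export
sense_codons <- function() {
  names(Biostrings::RNA_GENETIC_CODE)[Biostrings::RNA_GENETIC_CODE != "*"]
}

#' Load a tRNA gene-copy-number table
#'
#' Reads a tab-separated file with header columns `anticodon`,
#' `amino_acid` and `copy_number`. Anticodons are RNA triplets written
#' 5'→3' (T is normalised to U on read); `amino_acid` is the one-letter
#' code of the charged amino acid; `copy_number` the genomic gene count,
#' used as a proxy for tRNA abundance.
#'
#' @param path path to the TSV file. Lines starting with `#` are ignored.
#' @return A `trna_copy_table`: a data frame with columns `anticodon`,
#'   `amino_acid`, `copy_number`.
#' @export
load_trna_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("anticodon", "amino_acid", "copy_number")
  if (!all(need %in% names(df)))
    stop("tRNA table must have columns: ", paste(need, collapse = ", "))
  trna_copy_table(df$anticodon, df$amino_acid, df$copy_number)
}

#' Construct a tRNA copy-number table
#'
#' @param anticodon character vector of RNA (or DNA) triplets, 5'→3'.
#' @param amino_acid one-letter amino-acid codes.
#' @param copy_number non-negative integer gene copy numbers.
#' @return A `trna_copy_table` data frame.
#' @export
trna_copy_table <- function(anticodon, amino_acid, copy_number) {
  anticodon <- chartr("Tt", "Uu", toupper(anticodon))
  bad <- nchar(anticodon) != 3 |
    !vapply(strsplit(anticodon, ""), function(b) all(b %in% RNA_BASES), TRUE)
  if (any(bad))
    stop("malformed anticodon triplet(s): ", paste(anticodon[bad], collapse = ", "))
  if (anyDuplicated(anticodon))
    stop("duplicate anticodon(s): ",
         paste(unique(anticodon[duplicated(anticodon)]), collapse = ", "))
  copy_number <- as.numeric(copy_number)
  if (any(!is.finite(copy_number)) || any(copy_number < 0))
    stop("copy numbers must be non-negative")
  out <- data.frame(anticodon = anticodon, amino_acid = toupper(amino_acid),
                    copy_number = copy_number, stringsAsFactors = FALSE)
  class(out) <- c("trna_copy_table", "data.frame")
  out
}

#' Wobble-pairing rules for third-position decoding
#'
#' Decoding requires Watson–Crick pairing at the first two codon positions
#' (anticodon positions 3 and 2, antiparallel). At the third codon
#' position, pairing with the anticodon's first (wobble) base is governed
#' by an efficiency-factor table: Watson–Crick pairs decode at factor 1,
#' non-canonical pairs at a reduced factor. The default rule set covers
#' the standard eukaryotic repertoire: G:U wobble in both orientations
#' and inosine-like reading by A-starting anticodons (I, derived from A,
#' reads U, C and A; the U reading is the Watson–Crick A:U pair).
#'
#' @param wobble_penalty efficiency factor in `[0, 1]` applied to all
#'   non-Watson–Crick pairings (default 0.5).
#' @param inosine if `TRUE` (default), anticodons starting with A
#'   additionally read codons ending in C and A at the wobble penalty.
#' @param extra named numeric vector of additional pairings, names of the
#'   form `"<codon 3rd base>:<anticodon 1st base>"`, values in `[0, 1]`;
#'   overrides defaults for matching keys.
#' @return A `wobble_rules` object: a named numeric vector of pairing
#'   factors keyed `"N:M"` (codon third base : anticodon first base).
#' @export
wobble_rules <- function(wobble_penalty = 0.5, inosine = TRUE, extra = NULL) {
  if (wobble_penalty < 0 || wobble_penalty > 1)
    stop("wobble_penalty must be in [0, 1]")
  p <- c("A:U" = 1, "U:A" = 1, "G:C" = 1, "C:G" = 1,   # Watson-Crick
         "U:G" = wobble_penalty,                        # anticodon G reads U
         "G:U" = wobble_penalty)                        # anticodon U reads G
  if (inosine)
    p <- c(p, "C:A" = wobble_penalty, "A:A" = wobble_penalty)
  if (!is.null(extra)) {
    if (any(extra < 0 | extra > 1)) stop("pairing factors must be in [0, 1]")
    p[names(extra)] <- extra
  }
  structure(p, class = "wobble_rules")
}

#' Decoding anticodons of a codon under a wobble rule set
#'
#' An anticodon (5'→3') decodes a codon (5'→3') when positions 1 and 2 of
#' the codon form Watson–Crick pairs with anticodon positions 3 and 2, and
#' the pairing key `codon[3]:anticodon[1]` appears in the rules. When
#' `amino_acid` is given, the anticodon must additionally be charged with
#' the codon's amino acid (cognate decoding only).
#'
#' @keywords internal
.pairing_factor <- function(codon, anticodon, rules) {
  cb <- strsplit(codon, "")[[1]]
  ab <- strsplit(anticodon, "")[[1]]
  if (ab[3] != .wc_partner[[cb[1]]] || ab[2] != .wc_partner[[cb[2]]])
    return(0)
  key <- paste0(cb[3], ":", ab[1])
  if (is.na(match(key, names(rules)))) 0 else unname(rules[[key]])
}

#' Build the codon → tRNA-capture-rate table
#'
#' For each sense codon c, the capture rate is
#' `k_c = scaling * sum_t copy_number(t) * pairing_factor(c, t)` over all
#' cognate anticodons t that decode c under the wobble rules. When
#' `scaling` is `NULL` it is calibrated so that the usage-weighted mean of
#' `k_c` equals `target_mean` (uniform usage weights by default), making
#' published copy-number tables plug-compatible with the simulation's
#' absolute time scale.
#'
#' @param trna a `trna_copy_table`.
#' @param wobble a `wobble_rules` object (default `wobble_rules()`).
#' @param scaling rate contributed per gene copy (s^-1); `NULL` to
#'   calibrate against `target_mean`.
#' @param target_mean target usage-weighted mean capture rate in s^-1
#'   (default 10), used only when `scaling` is `NULL`.
#' @param usage optional named numeric vector of codon-usage weights for
#'   the calibration; defaults to uniform over the sense codons.
#' @param require_cognate if `TRUE` (default), an anticodon contributes
#'   only to codons of its own amino acid, excluding near-cognate
#'   mispairings that cross amino-acid identity.
#' @return A `rate_table`: list with `rates` (named numeric over the 61
#'   sense codons, all > 0) and `scaling_constant`.
#' @export
#' @examples
#' tab <- trna_copy_table("UUU", "K", 10)
#' rt <- build_rate_table(tab, wobble_rules(), scaling = 1)
#' rt$rates[["AAA"]]  # Watson-Crick: 10
#' rt$rates[["AAG"]]  # G:U wobble:   5
build_rate_table <- function(trna, wobble = wobble_rules(), scaling = NULL,
                             target_mean = 10, usage = NULL,
                             require_cognate = TRUE) {
  stopifnot(inherits(trna, "trna_copy_table"))
  codons <- sense_codons()
  aa <- .codon_aa(codons)
  k <- setNames(numeric(length(codons)), codons)
  for (i in seq_along(codons)) {
    for (j in seq_len(nrow(trna))) {
      if (require_cognate && trna$amino_acid[j] != aa[i]) next
      f <- .pairing_factor(codons[i], trna$anticodon[j], wobble)
      k[i] <- k[i] + trna$copy_number[j] * f
    }
  }
  undec <- codons[k <= 0]
  if (length(undec))
    stop("codon(s) not decodable by any anticodon in the table: ",
         paste(undec, collapse = ", "))
  if (is.null(scaling)) {
    if (is.null(usage)) usage <- setNames(rep(1, length(codons)), codons)
    w <- usage[codons]
    w[is.na(w)] <- 0
    scaling <- target_mean / sum(k * w / sum(w))
  }
  structure(list(rates = k * scaling, scaling_constant = scaling),
            class = "rate_table")
}

#' Construct a rate table directly from per-codon rates
#'
#' Mainly for synthetic experiments where the per-codon capture rates are
#' specified rather than derived from a tRNA census.
#'
#' @param rates named numeric vector, names a subset of the sense codons
#'   plus optionally nothing else; all values > 0. Codons absent from
#'   `rates` take `default`, unless `default` is `NA` in which case the
#'   table covers only the named codons.
#' @param default rate for unnamed sense codons (default `NA`).
#' @return A `rate_table`.
#' @export
rate_table <- function(rates, default = NA_real_) {
  codons <- sense_codons()
  bad <- setdiff(names(rates), codons)
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  if (any(rates <= 0)) stop("all rates must be > 0")
  full <- setNames(rep(default, length(codons)), codons)
  full[names(rates)] <- rates
  full <- full[!is.na(full)]
  structure(list(rates = full, scaling_constant = 1),
            class = "rate_table")
}

#' Map an ORF to its per-codon capture-rate profile
#'
#' The ORF must be an in-frame coding-strand sequence beginning with AUG;
#' a terminal stop codon is allowed and stripped. The profile covers codon
#' positions 1..L where L is the ORF length in codons excluding the stop.
#'
#' @param orf a nucleotide string (RNA or DNA, any case) or a character
#'   vector of codons.
#' @param table a `rate_table`.
#' @param gene_id identifier stored in the profile.
#' @return A `rate_profile`: list with `gene_id`, `codons` (length L) and
#'   `k` (numeric, s^-1, length L).
#' @export
rate_profile <- function(orf, table, gene_id = "orf") {
  stopifnot(inherits(table, "rate_table"))
  codons <- as_codons(orf)
  stops <- c("UAA", "UAG", "UGA")
  if (codons[1] != "AUG")
    stop("ORF must start with AUG (got ", codons[1], ")")
  if (codons[length(codons)] %in% stops)
    codons <- codons[-length(codons)]
  internal <- which(codons %in% stops)
  if (length(internal))
    stop("internal stop codon at codon position(s): ",
         paste(internal, collapse = ", "))
  miss <- setdiff(unique(codons), names(table$rates))
  if (length(miss))
    stop("codon(s) missing from rate table: ", paste(miss, collapse = ", "))
  k <- unname(table$rates[codons])
  structure(list(gene_id = gene_id, codons = codons, k = k),
            class = "rate_profile")
}

#' Split a nucleotide sequence into RNA codons
#'
#' @param x a nucleotide string or a character vector of codons; T is
#'   normalised to U and case is folded.
#' @return Character vector of codons.
#' @export
as_codons <- function(x) {
  if (length(x) == 1 && nchar(x) > 3) {
    s <- chartr("Tt", "Uu", toupper(x))
    if (nchar(s) %% 3 != 0)
      stop("sequence length ", nchar(s), " is not divisible by 3")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  } else {
    codons <- chartr("Tt", "Uu", toupper(x))
  }
  ok <- nchar(codons) == 3 &
    vapply(strsplit(codons, ""), function(b) all(b %in% RNA_BASES), TRUE)
  if (!all(ok))
    stop("invalid codon(s): ", paste(unique(codons[!ok]), collapse = ", "))
  codons
}

#' @export
print.rate_profile <- function(x, ...) {
  cat("<rate_profile> ", x$gene_id, ": L = ", length(x$k),
      " codons, k in [", signif(min(x$k), 3), ", ", signif(max(x$k), 3),
      "] s^-1\n", sep = "")
  invisible(x)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> ", length(x$rates), " codons, scaling = ",
      signif(x$scaling_constant, 4), " s^-1 per copy, mean k = ",
      signif(mean(x$rates), 4), " s^-1\n", sep = "")
  invisible(x)
}

#' Export a rate table as TSV
#'
#' @param table a `rate_table`.
#' @param path output path; columns `codon`, `k`.
#' @export
write_rate_table <- function(table, path) {
  df <- data.frame(codon = names(table$rates), k = unname(table$rates))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
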