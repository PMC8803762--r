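# Shared helpers: genetic-code access, Jukes-Cantor transforms, seeded RNG
# streams, percentage formatting.

.codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    .codon_env$code <- Biostrings::GENETIC_CODE
  }
  .codon_env$code
}

#' @keywords internal
translate_codon <- function(codon) {
  genetic_code()[[codon]]
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be a multiple of 3, got ", n)
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

# Errors on internal stop codons; a single trailing stop is trimmed.
check_cds <- function(cds, id = "sequence") {
  codons <- split_codons(toupper(cds))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) stop("non-ACGT codon in ", id)
  stops <- which(aa == "*")
  if (length(stops) > 0 && !identical(stops, length(codons))) {
    stop("internal stop codon in ", id, " at codon ", stops[1])
  }
  if (length(stops) == 1 && stops == length(codons)) codons <- codons[-length(codons)]
  codons
}

# Jukes-Cantor multiple-hit correction of a raw difference proportion.
jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Raw proportion that a JC-corrected distance d implies.
jc_inverse <- function(d) {
  0.75 * (1 - exp(-4 * d / 3))
}

# Round half-up, matching the reporting convention for percentages.
half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct <- function(count, total) {
  if (length(total) == 0 || is.na(total) || total == 0) return(NA_real_)
  half_up(100 * count / total, 2)
}

# Evaluate expr under a fixed seed and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Named substreams off one root seed so adding a generator does not perturb
# the draws of the others. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

species_of <- function(ids) {
  sub("\\|.*$", "", ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
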