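# Internal helpers shared across modules.

# Amino-acid vocabulary: 20 standard residues plus ambiguity codes.
.aa_ambiguous <- c("X", "B", "Z", "U")
.aa_valid <- NULL  # filled in .onLoad-free way below

.valid_residues <- function() c(.aa_alphabet, .aa_ambiguous)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical isozyme vocabulary (Latin) with accepted synonyms (Greek letters).
.isozyme_names <- c("alpha", "beta", "gamma", "delta", "epsilon",
                    "zeta", "eta", "theta", "iota", "kappa")

.isozyme_synonyms <- c(
  "α" = "alpha",  "β" = "beta",  "γ" = "gamma",
  "δ" = "delta",  "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta",    "θ" = "theta", "ι" = "iota",
  "κ" = "kappa",
  # occasional Greek variants seen in the literature
  "ί" = "iota"
)

.taxon_groups <- c("mammal", "bird", "reptile", "amphibian", "fish", "other")

#' Canonicalise an isozyme token
#'
#' Accepts Latin names (`"alpha"` ... `"kappa"`), single Greek letters, or
#' `"unknown"`; anything else is an error.
#'
#' @param x character vector of isozyme tokens.
#' @return character vector of canonical Latin isozyme names (or `"unknown"`).
#' @export
canonical_isozyme <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% names(.isozyme_synonyms), .isozyme_synonyms[x], x)
  out[out == "" | is.na(out)] <- "unknown"
  bad <- setdiff(unique(out), c(.isozyme_names, "unknown"))
  if (length(bad))
    .stopf("unknown isozyme name(s): %s (expected alpha...kappa, Greek letters, or 'unknown')",
           paste(bad, collapse = ", "))
  unname(out)
}

# Fixed isozyme -> class scheme: I {alpha,beta,gamma}, II {delta,eta,kappa},
# III {epsilon}, IV {zeta,iota}, V {theta}.
.isozyme_class_map <- c(
  alpha = "I", beta = "I", gamma = "I",
  delta = "II", eta = "II", kappa = "II",
  epsilon = "III",
  zeta = "IV", iota = "IV",
  theta = "V"
)

#' Class of a DGK isozyme
#'
#' Applies the fixed ten-isozyme / five-class scheme used for diacylglycerol
#' kinases: class I = alpha, beta, gamma; II = delta, eta, kappa;
#' III = epsilon; IV = zeta, iota; V = theta.
#'
#' @param isozyme character vector of isozyme names (Latin or Greek).
#' @return character vector of classes `"I"`..`"V"`, or `"unknown"`.
#' @export
#' @examples
#' isozyme_class(c("epsilon", "ζ", "unknown"))
isozyme_class <- function(isozyme) {
  iso <- canonical_isozyme(isozyme)
  out <- ifelse(iso %in% names(.isozyme_class_map),
                .isozyme_class_map[iso], "unknown")
  unname(out)
}
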