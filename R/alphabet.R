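# Internal alphabet and substitution-matrix helpers shared by all modules.

#' @useDynLib tandemaaa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical 20-letter amino-acid alphabet; X is the 21st (unknown) code
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AAX <- c(AA20, "X")

# letters tolerated on input and mapped to X (selenocysteine, pyrrolysine,
# ambiguity codes, stop/unknown marks)
AA_MAP_TO_X <- c("U", "O", "B", "Z", "J", "*", "?")

# Robinson & Robinson style background amino-acid frequencies (order AA20)
AA_BACKGROUND <- c(
  A = 0.0787, C = 0.0151, D = 0.0535, E = 0.0668, F = 0.0397,
  G = 0.0695, H = 0.0229, I = 0.0590, K = 0.0581, L = 0.0963,
  M = 0.0239, N = 0.0409, P = 0.0484, Q = 0.0396, R = 0.0540,
  S = 0.0683, T = 0.0541, V = 0.0673, W = 0.0114, Y = 0.0304
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# encode residues as 0-based integer codes (X -> 20, gap '-' -> -1)
aa_encode <- function(x) {
  stopifnot(length(x) == 1L)
  chars <- strsplit(toupper(x), "")[[1]]
  code <- match(chars, AAX) - 1L
  code[chars == "-"] <- -1L
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("non-amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  code
}

aa_decode <- function(code) {
  out <- rep("-", length(code))
  out[code >= 0] <- AAX[code[code >= 0] + 1L]
  paste(out, collapse = "")
}

# sanitize a raw residue string: uppercase, map uncommon letters to X
# (with one warning), reject everything else
aa_sanitize <- function(x, map_to_x = TRUE, context = "") {
  x <- toupper(x)
  chars <- strsplit(x, "")[[1]]
  unknown <- !(chars %in% AAX)
  if (any(unknown)) {
    mappable <- chars[unknown] %in% AA_MAP_TO_X
    if (!map_to_x || !all(mappable)) {
      bad <- unique(chars[unknown][!(chars[unknown] %in% AA_MAP_TO_X) | !map_to_x])
      stop("non-amino-acid letter(s) ", paste(bad, collapse = ", "),
           if (nzchar(context)) paste0(" in ", context))
    }
    warning("mapped ", sum(unknown), " uncommon letter(s) to X",
            if (nzchar(context)) paste0(" in ", context), call. = FALSE)
    chars[unknown] <- "X"
    x <- paste(chars, collapse = "")
  }
  x
}

# BLOSUM62 over AAX: 21 x 21 with X rows/cols = 0
blosum62_aax <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b <- e$BLOSUM62[AA20, AA20]
      m <- matrix(0, 21, 21, dimnames = list(AAX, AAX))
      m[1:20, 1:20] <- b
      cache <<- m
    }
    cache
  }
})
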