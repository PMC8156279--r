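#' Fold an RNA sequence into a secondary structure
#'
#' Predicts a minimum-energy secondary structure for a candidate precursor.
#' Two engines are available:
#'
#' * `"fallback"` (default): the bundled deterministic maximum base-pairing
#'   fold (Nussinov recursion) with a minimum hairpin loop of 3 nt,
#'   canonical Watson-Crick plus G:U pairs, and "energy" reported as minus
#'   the number of base pairs, in arbitrary units. Being self-contained and
#'   bit-reproducible, it is the engine used by the synthetic-panel
#'   verification and the test suite.
#' * `"thermo"`: thermodynamic MFE folding through the ViennaRNA `RNAfold`
#'   executable when it is on the `PATH`; energies are kcal/mol.
#'
#' The engine identity is carried in the returned object (and propagated
#' into all locus tables) because structures and energy scales are not
#' comparable across engines.
#'
#' @param seq a single RNA string (A/C/G/U; N allowed but never pairs),
#'   length >= 15.
#' @param engine `"fallback"` or `"thermo"`.
#' @param blocked optional integer vector of 1-based positions forbidden
#'   from pairing (used for target-site accessibility).
#' @return an object of class `rna_structure`: a list with `dotbracket`,
#'   `mfe`, `pair_table` (1-based partner index, 0 = unpaired) and
#'   `engine`.
#' @examples
#' fold("GGGGGGGGGGAAAACCCCCCCCCC")
#' @export
fold <- function(seq, engine = c("fallback", "thermo"), blocked = NULL) {
  engine <- match.arg(engine)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n < 15) stop("sequence too short to fold (< 15 nt)")
  if (grepl("[^ACGUN]", seq)) stop("non-RNA alphabet in sequence")
  blk <- rep(FALSE, n)
  if (!is.null(blocked)) {
    blocked <- as.integer(blocked)
    if (any(blocked < 1 | blocked > n)) stop("blocked positions out of range")
    blk[blocked] <- TRUE
  }
  if (engine == "fallback") {
    db <- .nussinov_fold_cpp(seq, blk, 3L)
    mfe <- -sum(strsplit(db, "", fixed = TRUE)[[1]] == "(")
  } else {
    res <- rnafold_run(seq, blk)
    db <- res$dotbracket
    mfe <- res$mfe
  }
  structure(list(dotbracket = db, mfe = mfe,
                 pair_table = pair_table(db), engine = engine),
            class = "rna_structure")
}

#' Pair table of a dot-bracket string
#'
#' @param dotbracket a dot-bracket string over `(`, `)`, `.`.
#' @return integer vector: position of the partner of each base (1-based),
#'   0 for unpaired. The mapping is an involution.
#' @export
pair_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket string")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pt
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure (", x$engine, " engine)\n", sep = "")
  cat(x$dotbracket, "\n")
  cat("energy: ", x$mfe,
      if (x$engine == "fallback") " (arbitrary units, -pairs)" else " kcal/mol",
      "\n", sep = "")
  invisible(x)
}

# Run ViennaRNA's RNAfold on one sequence, optionally with unpaired
# constraints at `blk` positions.
rnafold_run <- function(seq, blk) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("RNAfold not found on PATH; use engine = \"fallback\"")
  }
  args <- c("--noPS")
  input <- seq
  if (any(blk)) {
    constraint <- paste(ifelse(blk, "x", "."), collapse = "")
    input <- c(seq, constraint)
    args <- c(args, "-C")
  }
  out <- system2(exe, args, input = input, stdout = TRUE, stderr = FALSE)
  line <- out[length(out)]
  m <- regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line)
  parts <- regmatches(line, m)[[1]]
  if (length(parts) != 3) stop("could not parse RNAfold output: ", line)
  list(dotbracket = parts[2], mfe = as.numeric(parts[3]))
}

# Hairpin (terminal) loops of a structure: maximal runs of unpaired
# positions whose immediate flanks pair with each other. Returns a list of
# c(start, end) 1-based inclusive intervals.
hairpin_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  i <- 1L
  while (i <= n) {
    if (pt[i] == 0L) {
      j <- i
      while (j < n && pt[j + 1L] == 0L) j <- j + 1L
      if (i > 1L && j < n && pt[i - 1L] == j + 1L) {
        loops[[length(loops) + 1L]] <- c(i, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  loops
}
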