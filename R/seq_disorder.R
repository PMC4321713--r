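# Kyte-Doolittle hydropathy scale (per residue).
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

.check_residues <- function(residues) {
  residues <- toupper(residues)
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(letters, c(names(.kd_scale), "X"))
  if (length(bad))
    stop("non-standard residue letters: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  letters
}

#' Construct a sequence record
#'
#' @param id Identifier.
#' @param residues One-letter amino-acid string (20 standard letters; `X`
#'   is tolerated and excluded from metrics).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues) {
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a single string", call. = FALSE)
  .check_residues(residues)
  structure(list(id = as.character(id), residues = toupper(residues)),
            class = "seq_record")
}

#' Read sequence records from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of [seq_record()] objects.
#' @export
read_fasta_records <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(i)
    seq_record(names(set)[i], as.character(set[[i]])))
}

.as_record <- function(seq) {
  if (inherits(seq, "seq_record")) seq
  else if (is.character(seq) && length(seq) == 1L) seq_record("seq", seq)
  else stop("expected a seq_record or a single sequence string",
            call. = FALSE)
}

#' Amino-acid composition
#'
#' Per-residue-type fractions (counts over sequence length); `X`
#' placeholders are excluded from both counts and denominator.
#'
#' @param seq A [seq_record()] or a sequence string.
#' @return Named numeric vector of fractions summing to 1, in decreasing
#'   order.
#' @export
aa_composition <- function(seq) {
  rec <- .as_record(seq)
  letters <- .check_residues(rec$residues)
  letters <- letters[letters != "X"]
  if (!length(letters)) stop("empty sequence", call. = FALSE)
  tab <- table(letters)
  frac <- as.numeric(tab) / length(letters)
  names(frac) <- names(tab)
  sort(frac, decreasing = TRUE)
}

#' Charge-hydropathy disorder metrics
#'
#' Uversky-style classification of a sequence as natively folded versus
#' intrinsically disordered. Mean hydropathy is the average over
#' 5-residue sliding windows of Kyte-Doolittle values rescaled to
#' \[0, 1\] via `(h + 4.5) / 9` (per-residue averaging available as an
#' alternative mode); mean net charge is `|#K + #R - #D - #E| / length`
#' at neutral pH (histidine neutral). The boundary line of the
#' charge-hydropathy plane is `R = 2.785 H - 1.151`; sequences above it
#' classify as disordered, on or below it as ordered.
#'
#' @param seq A [seq_record()] or sequence string, length >= 5.
#' @param window Sliding-window width (default 5).
#' @param mode `"windowed"` (default) or `"per_residue"` hydropathy
#'   averaging.
#' @return An object of class `disorder_metrics`: `mean_hydropathy`,
#'   `mean_net_charge`, `boundary_charge` (boundary value at the
#'   sequence's hydropathy), `boundary_distance` (net charge minus
#'   boundary; positive means disordered side), `classification`
#'   (`"ordered-region"` or `"disordered-region"`), `composition`.
#' @export
uversky_metrics <- function(seq, window = 5L,
                            mode = c("windowed", "per_residue")) {
  mode <- match.arg(mode)
  rec <- .as_record(seq)
  letters <- .check_residues(rec$residues)
  known <- letters[letters != "X"]
  if (length(known) < window)
    stop(sprintf("sequence must have at least %d standard residues", window),
         call. = FALSE)
  h <- (.kd_scale[known] + 4.5) / 9
  H <- if (mode == "windowed") {
    wm <- stats::filter(h, rep(1 / window, window), sides = 2)
    mean(wm[!is.na(wm)])
  } else mean(h)
  R <- abs(sum(known %in% c("K", "R")) - sum(known %in% c("D", "E"))) /
    length(known)
  structure(list(
    mean_hydropathy = as.numeric(H), mean_net_charge = R,
    boundary_charge = uversky_boundary(H),
    boundary_distance = R - uversky_boundary(H),
    classification = uversky_classify(H, R),
    composition = aa_composition(rec)
  ), class = "disorder_metrics")
}

#' Boundary of the charge-hydropathy plane
#'
#' @param mean_hydropathy Mean rescaled hydropathy `H`.
#' @return The net charge `2.785 H - 1.151` on the folded/disordered
#'   boundary at that hydropathy.
#' @export
uversky_boundary <- function(mean_hydropathy)
  2.785 * mean_hydropathy - 1.151

#' Classify a point of the charge-hydropathy plane
#'
#' @param mean_hydropathy,mean_net_charge Coordinates of the sequence.
#' @return `"disordered-region"` if the net charge exceeds the boundary
#'   `2.785 H - 1.151`, else `"ordered-region"` (points exactly on the
#'   boundary are assigned to the ordered side).
#' @export
uversky_classify <- function(mean_hydropathy, mean_net_charge) {
  if (mean_net_charge > uversky_boundary(mean_hydropathy))
    "disordered-region" else "ordered-region"
}

#' @export
print.disorder_metrics <- function(x, ...) {
  cat(sprintf("H = %.3f, R = %.4f (boundary %.4f) -> %s\n",
              x$mean_hydropathy, x$mean_net_charge, x$boundary_charge,
              x$classification))
  invisible(x)
}

#' Scan a sequence for a motif with X wildcards
#'
#' Finds all (possibly overlapping) occurrences of a motif such as
#' `GXGQQ`, where `X` matches any residue. Positions are 1-based.
#'
#' @param seq A [seq_record()] or sequence string (may be empty).
#' @param pattern Non-empty motif string.
#' @return Integer vector of 1-based start positions.
#' @export
scan_motif <- function(seq, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("'pattern' must be a non-empty string", call. = FALSE)
  residues <- if (inherits(seq, "seq_record")) seq$residues
              else toupper(as.character(seq))
  if (!nzchar(residues)) return(integer(0))
  rx <- gsub("X", ".", toupper(pattern), fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), residues, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}
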