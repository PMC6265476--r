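# Structural requirements and built-in presets.
#
# A StructuralRequirements object captures the rule set applied around each
# profile-HMM hit: on which side the partner gene is searched (relative to
# the hit's direction of transcription), the permitted protein lengths of
# hit and partner, and the permitted intergenic distance / overlap in bp.

#' Construct a structural-requirements rule set
#'
#' @param orientation where the partner is required: `"upstream"`,
#'   `"downstream"`, `"either"` (one side suffices; both attached when both
#'   qualify) or `"both"` (three-component array, one partner each side).
#' @param hit_min_aa,hit_max_aa permitted protein length of the conserved
#'   (hit) gene, in amino acids.
#' @param partner_min_aa_up,partner_max_aa_up,partner_min_aa_down,partner_max_aa_down
#'   permitted partner lengths per side (aa).
#' @param max_distance_bp maximum intergenic gap between hit and partner.
#' @param max_overlap_bp maximum permitted overlap between hit and partner.
#' @return object of class `structural_requirements`.
#' @export
structural_requirements <- function(orientation = c("either", "upstream",
                                                    "downstream", "both"),
                                    hit_min_aa, hit_max_aa,
                                    partner_min_aa_up, partner_max_aa_up,
                                    partner_min_aa_down = partner_min_aa_up,
                                    partner_max_aa_down = partner_max_aa_up,
                                    max_distance_bp, max_overlap_bp) {
  orientation <- match.arg(orientation)
  req <- structure(list(
    orientation = orientation,
    hit_min_aa = as.integer(hit_min_aa), hit_max_aa = as.integer(hit_max_aa),
    partner_min_aa_up = as.integer(partner_min_aa_up),
    partner_max_aa_up = as.integer(partner_max_aa_up),
    partner_min_aa_down = as.integer(partner_min_aa_down),
    partner_max_aa_down = as.integer(partner_max_aa_down),
    max_distance_bp = as.integer(max_distance_bp),
    max_overlap_bp = as.integer(max_overlap_bp)),
    class = "structural_requirements")
  validate_requirements(req)
  req
}

#' Validate a structural-requirements object
#' @param req a `structural_requirements`.
#' @return `req`, invisibly; errors on violated invariants.
#' @export
validate_requirements <- function(req) {
  stopifnot(inherits(req, "structural_requirements"))
  with(req, {
    if (hit_min_aa > hit_max_aa)
      stop("hit_min_aa > hit_max_aa")
    if (partner_min_aa_up > partner_max_aa_up)
      stop("partner_min_aa_up > partner_max_aa_up")
    if (partner_min_aa_down > partner_max_aa_down)
      stop("partner_min_aa_down > partner_max_aa_down")
    if (max_distance_bp < 0) stop("max_distance_bp must be >= 0")
    if (max_overlap_bp < 0) stop("max_overlap_bp must be >= 0")
  })
  invisible(req)
}

#' @export
print.structural_requirements <- function(x, ...) {
  cat(sprintf(paste0(
    "<structural_requirements> orientation=%s\n",
    "  hit length      %d-%d aa\n",
    "  partner length  up %d-%d aa / down %d-%d aa\n",
    "  max distance    %d bp, max overlap %d bp\n"),
    x$orientation, x$hit_min_aa, x$hit_max_aa,
    x$partner_min_aa_up, x$partner_max_aa_up,
    x$partner_min_aa_down, x$partner_max_aa_down,
    x$max_distance_bp, x$max_overlap_bp))
  invisible(x)
}

#' Load a built-in preset
#'
#' Three parameterisations ship with the package:
#' \describe{
#'   \item{TA}{type II toxin-antitoxin screening: partner on either side,
#'     toxin 30-200 aa, antitoxin 50-150 aa, gap at most 50 bp, overlap at
#'     most 20 bp, and a default expected-length deviation of 100 aa for
#'     profile-specific length filtering.}
#'   \item{RND}{RND efflux pumps: the membrane fusion protein is encoded
#'     upstream of the pump, pump 700-1500 aa, partner 100-1000 aa, gap at
#'     most 500 bp, overlap at most 20 bp.}
#'   \item{flex}{structure unknown: nearest neighbouring gene on either
#'     side, essentially unbounded lengths, distance/overlap capped at
#'     300 bp to keep "nearest" biologically meaningful.}
#' }
#'
#' @param name one of `"TA"`, `"RND"`, `"flex"`.
#' @return object of class `preset` with fields `name`, `requirements`,
#'   `min_bitscore`, `expected_length_deviation`.
#' @export
load_preset <- function(name) {
  presets <- list(
    TA = list(
      requirements = structural_requirements(
        orientation = "either", hit_min_aa = 30, hit_max_aa = 200,
        partner_min_aa_up = 50, partner_max_aa_up = 150,
        max_distance_bp = 50, max_overlap_bp = 20),
      min_bitscore = 20, expected_length_deviation = 100L),
    RND = list(
      requirements = structural_requirements(
        orientation = "upstream", hit_min_aa = 700, hit_max_aa = 1500,
        partner_min_aa_up = 100, partner_max_aa_up = 1000,
        max_distance_bp = 500, max_overlap_bp = 20),
      min_bitscore = 20, expected_length_deviation = NULL),
    flex = list(
      requirements = structural_requirements(
        orientation = "either", hit_min_aa = 1, hit_max_aa = 1e6,
        partner_min_aa_up = 1, partner_max_aa_up = 1e6,
        max_distance_bp = 300, max_overlap_bp = 300),
      min_bitscore = 20, expected_length_deviation = NULL)
  )
  if (!is.character(name) || length(name) != 1L || !(name %in% names(presets)))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  structure(list(name = name, requirements = p$requirements,
                 min_bitscore = p$min_bitscore,
                 expected_length_deviation = p$expected_length_deviation),
            class = "preset")
}

#' Override fields of a preset's requirements
#'
#' Named presets are immutable; overriding produces a new
#' `structural_requirements` whose invariants are re-validated.
#'
#' @param base a `preset` or `structural_requirements`.
#' @param overrides named list of field replacements
#'   (e.g. `list(max_distance_bp = 500)`).
#' @return a new `structural_requirements`.
#' @export
merge_requirements <- function(base, overrides = list()) {
  req <- if (inherits(base, "preset")) base$requirements else base
  stopifnot(inherits(req, "structural_requirements"))
  if (length(overrides) == 0L) return(req)
  bad <- setdiff(names(overrides), names(unclass(req)))
  if (length(bad))
    stop("unknown requirement field(s): ", paste(bad, collapse = ", "))
  out <- unclass(req)
  for (k in names(overrides)) {
    out[[k]] <- if (k == "orientation") as.character(overrides[[k]])
                else as.integer(overrides[[k]])
  }
  out <- structure(out, class = "structural_requirements")
  if (!(out$orientation %in% c("either", "upstream", "downstream", "both")))
    stop("invalid orientation '", out$orientation, "'")
  validate_requirements(out)
  out
}

#' Parse a profile expected-length table
#'
#' Two or three whitespace/tab-separated columns: profile name, expected
#' protein length (aa) and optionally a per-profile maximum deviation; the
#' global deviation applies where the third column is absent.
#'
#' @param path table file; `#` lines are comments. An empty file yields an
#'   empty map (the length filter is then vacuous).
#' @param default_deviation_aa global maximum deviation (aa).
#' @return data.frame with columns `profile`, `expected_aa`,
#'   `max_deviation_aa`.
#' @export
parse_expected_lengths <- function(path, default_deviation_aa = 100L) {
  if (!file.exists(path)) stop("expected-lengths file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  proto <- data.frame(profile = character(), expected_aa = integer(),
                      max_deviation_aa = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(proto)
  parts <- strsplit(trimws(lines), "[ \t]+")
  rows <- lapply(parts, function(f) {
    if (length(f) < 2L)
      stop("expected-lengths row needs at least 2 columns: ",
           paste(f, collapse = " "))
    exp_aa <- suppressWarnings(as.integer(f[2]))
    dev_aa <- if (length(f) >= 3L) suppressWarnings(as.integer(f[3]))
              else as.integer(default_deviation_aa)
    if (is.na(exp_aa) || is.na(dev_aa))
      stop("non-numeric value in expected-lengths row: ",
           paste(f, collapse = " "))
    if (exp_aa <= 0L || dev_aa < 0L)
      stop("expected length must be positive and deviation non-negative: ",
           paste(f, collapse = " "))
    data.frame(profile = f[1], expected_aa = exp_aa, max_deviation_aa = dev_aa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$profile))
    stop("duplicate profile row(s) in expected-lengths file: ",
         paste(unique(out$profile[duplicated(out$profile)]), collapse = ", "))
  rownames(out) <- NULL
  out
}
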