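# FAME shorthand parsing, methyl-ester molecular weights and class totals.
#
# Notation dialect accepted on input is liberal: the leading "C" is optional
# ("16:1n7c"), the omega marker may be "n" or the Greek omega ("C18:2ω6"),
# geometry is a trailing "c"/"t" with or without an omega locant ("C20:3c"),
# and a trailing word ("alpha") is kept as a free-text qualifier.  Output is
# always the canonical "C{carbons}:{bonds}[n{omega}][c|t][ qualifier]" form.

# Fixed atomic masses; held constant for reproducibility rather than tracking
# CODATA revisions.
.FAME_ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

.fame_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "famefuel_error")))
}

#' Parse a FAME shorthand token
#'
#' Parses lipid shorthand such as `"C18:1n9t"` into its structural fields:
#' acyl-chain carbon count, number of carbon-carbon double bonds, optional
#' omega (n-x) locant, double-bond geometry and an optional free-text
#' qualifier.
#'
#' @param token Character scalar, e.g. `"C16:0"`, `"16:1n7c"`, `"C18:2ω6"`,
#'   `"C18:3 alpha"`.
#' @param weight_percent Optional weight percent (share of total FAME mass)
#'   to attach to the species.
#'
#' @return A `fame_species` object: a list with fields `notation` (canonical
#'   form), `carbons`, `double_bonds`, `omega` (integer or `NA`), `geometry`
#'   (`"cis"`, `"trans"` or `"unspecified"`), `qualifier` (character or `NA`)
#'   and `weight_percent` (numeric or `NA`).
#'
#' @examples
#' parse_fame_notation("C18:1n9t")
#' parse_fame_notation("16:1n7c")$geometry
#' @export
parse_fame_notation <- function(token, weight_percent = NA_real_) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    .fame_error("FAME token must be a single character string",
                "famefuel_parse_error")
  }
  raw <- trimws(token)
  if (!nzchar(raw)) {
    .fame_error("empty FAME token", "famefuel_parse_error")
  }
  pat <- paste0("^[Cc]?([0-9]+):([0-9]+)",       # carbons:double bonds
                "(?:[n\u03c9]([0-9]+))?",        # omega marker: "n" or Greek omega
                "([ct])?",                       # optional geometry letter
                "(?:[ _-]+([A-Za-z][A-Za-z0-9-]*))?$") # optional qualifier
  m <- regmatches(raw, regexec(pat, raw))[[1]]
  if (length(m) == 0L) {
    .fame_error(sprintf("malformed FAME token: '%s'", token),
                "famefuel_parse_error")
  }
  carbons <- as.integer(m[2])
  bonds   <- as.integer(m[3])
  if (carbons < 2L) {
    .fame_error(sprintf("FAME token '%s': acyl chain must have >= 2 carbons",
                        token), "famefuel_parse_error")
  }
  if (bonds >= carbons) {
    .fame_error(sprintf("FAME token '%s': %d double bonds impossible in a C%d chain",
                        token, bonds, carbons), "famefuel_parse_error")
  }
  omega <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  geometry <- switch(m[5], c = "cis", t = "trans", "unspecified")
  qualifier <- if (nzchar(m[6])) m[6] else NA_character_
  if (!is.na(weight_percent) &&
      (weight_percent < 0 || weight_percent > 100)) {
    .fame_error(sprintf("weight percent %g outside [0, 100]", weight_percent),
                "famefuel_value_error")
  }
  sp <- structure(
    list(notation = NA_character_, carbons = carbons, double_bonds = bonds,
         omega = omega, geometry = geometry, qualifier = qualifier,
         weight_percent = as.numeric(weight_percent)),
    class = "fame_species")
  sp$notation <- format_fame_notation(sp)
  sp
}

#' Canonical shorthand for a parsed FAME species
#'
#' Emits the single output dialect `"C{carbons}:{bonds}"` plus `"n{omega}"`,
#' a geometry letter and a space-separated qualifier where present.  The
#' canonical form re-parses to an equal species.
#'
#' @param species A `fame_species` object.
#' @return Character scalar.
#' @export
format_fame_notation <- function(species) {
  stopifnot(inherits(species, "fame_species"))
  out <- sprintf("C%d:%d", species$carbons, species$double_bonds)
  if (!is.na(species$omega)) out <- paste0(out, "n", species$omega)
  geo <- switch(species$geometry, cis = "c", trans = "t", "")
  out <- paste0(out, geo)
  if (!is.na(species$qualifier)) out <- paste(out, species$qualifier)
  out
}

#' @export
print.fame_species <- function(x, ...) {
  cat(sprintf("<fame_species> %s  (C=%d, D=%d, %s%s)%s\n",
              x$notation, x$carbons, x$double_bonds, x$geometry,
              if (is.na(x$omega)) "" else sprintf(", n-%d", x$omega),
              if (is.na(x$weight_percent)) ""
              else sprintf("  %.2f wt%%", x$weight_percent)))
  invisible(x)
}

#' Molecular weight of a fatty acid methyl ester
#'
#' The methyl ester of an acyl chain with `C` carbons and `D` double bonds
#' has formula C\[C+1\]H\[2(C+1)-2D\]O2; its mass is assembled from fixed
#' atomic masses (C 12.011, H 1.008, O 15.999).  Geometry and omega position
#' do not affect the mass.
#'
#' @param species A `fame_species`, or an integer carbon count when
#'   `double_bonds` is given.
#' @param double_bonds Number of double bonds when `species` is a plain
#'   carbon count.
#' @return Molecular weight in g/mol.
#'
#' @examples
#' fame_molecular_weight(parse_fame_notation("C16:0"))  # 270.46
#' @export
fame_molecular_weight <- function(species, double_bonds = NULL) {
  if (inherits(species, "fame_species")) {
    carbons <- species$carbons
    bonds <- species$double_bonds
  } else {
    carbons <- as.numeric(species)
    bonds <- as.numeric(double_bonds)
  }
  n_c <- carbons + 1
  n_h <- 2 * (carbons + 1) - 2 * bonds
  unname(.FAME_ATOMIC_MASS["C"] * n_c +
         .FAME_ATOMIC_MASS["H"] * n_h +
         .FAME_ATOMIC_MASS["O"] * 2)
}

#' Saturation class of a FAME species
#'
#' @param species A `fame_species`, or an integer vector of double-bond
#'   counts.
#' @return `"SFA"` (no double bonds), `"MUFA"` (one) or `"PUFA"` (two or
#'   more); vectorized over double-bond counts.
#' @export
saturation_class <- function(species) {
  d <- if (inherits(species, "fame_species")) species$double_bonds
       else as.integer(species)
  ifelse(d == 0L, "SFA", ifelse(d == 1L, "MUFA", "PUFA"))
}

#' Construct a FAME profile
#'
#' A profile is one sample's FAME composition: an ordered set of species with
#' weight percents.  Percentages are kept as reported — no renormalization to
#' 100 is performed, so class totals are raw sums.
#'
#' @param sample_id Sample identifier.
#' @param species Either a list of `fame_species` (with `weight_percent`
#'   set) or a data frame with columns `notation` and `weight_percent`.
#' @param medium Growth-medium label; defaults to `sample_id`.
#' @param sum_tolerance Allowed excess of the summed weight percent over 100.
#'
#' @return A `fame_profile` object with fields `sample_id`, `medium` and
#'   `species` (a data frame: notation, carbons, double_bonds, omega,
#'   geometry, qualifier, weight_percent).
#' @export
fame_profile <- function(sample_id, species, medium = sample_id,
                         sum_tolerance = 0.5) {
  if (is.data.frame(species)) {
    species <- Map(parse_fame_notation, species$notation,
                   species$weight_percent)
  }
  tab <- do.call(rbind, lapply(species, function(sp) {
    stopifnot(inherits(sp, "fame_species"))
    data.frame(notation = sp$notation, carbons = sp$carbons,
               double_bonds = sp$double_bonds, omega = sp$omega,
               geometry = sp$geometry, qualifier = sp$qualifier,
               weight_percent = sp$weight_percent,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(notation = character(), carbons = integer(),
                      double_bonds = integer(), omega = integer(),
                      geometry = character(), qualifier = character(),
                      weight_percent = numeric(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$notation)) {
    .fame_error(sprintf("duplicate species in profile '%s': %s", sample_id,
                        paste(unique(tab$notation[duplicated(tab$notation)]),
                              collapse = ", ")),
                "famefuel_profile_error")
  }
  if (nrow(tab) && anyNA(tab$weight_percent)) {
    .fame_error(sprintf("profile '%s' has species without weight percent",
                        sample_id), "famefuel_profile_error")
  }
  total <- sum(tab$weight_percent)
  if (total > 100 + sum_tolerance) {
    .fame_error(sprintf("profile '%s' weight percents sum to %.2f > 100 + %.2f",
                        sample_id, total, sum_tolerance),
                "famefuel_profile_error")
  }
  structure(list(sample_id = sample_id, medium = medium, species = tab),
            class = "fame_profile")
}

#' @export
print.fame_profile <- function(x, ...) {
  cat(sprintf("<fame_profile> %s (medium %s): %d species, %.1f wt%% total\n",
              x$sample_id, x$medium, nrow(x$species),
              sum(x$species$weight_percent)))
  print(x$species[, c("notation", "weight_percent")], row.names = FALSE)
  invisible(x)
}

#' Saturation-class totals of a FAME profile
#'
#' Sums weight percents by saturation class, without renormalization.  The
#' unsaturated total is MUFA + PUFA and the SFA/UFA ratio is reported as `NA`
#' (with `ratio_defined = FALSE`) for an all-saturated or empty profile.
#'
#' @param profile A `fame_profile`.
#' @return A `fame_class_totals` object: list with `sfa`, `mufa`, `pufa`,
#'   `ufa` (weight percents), `sfa_ufa_ratio` and `ratio_defined`.
#'
#' @examples
#' pw <- read_fame_csv(system.file("extdata", "table2_fame.csv",
#'                                 package = "famefuel"))[["PW"]]
#' class_totals(pw)
#' @export
class_totals <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  cls <- saturation_class(profile$species$double_bonds)
  wt <- profile$species$weight_percent
  sfa <- sum(wt[cls == "SFA"])
  mufa <- sum(wt[cls == "MUFA"])
  pufa <- sum(wt[cls == "PUFA"])
  ufa <- mufa + pufa
  structure(list(sfa = sfa, mufa = mufa, pufa = pufa, ufa = ufa,
                 sfa_ufa_ratio = if (ufa > 0) sfa / ufa else NA_real_,
                 ratio_defined = ufa > 0),
            class = "fame_class_totals")
}

#' @export
print.fame_class_totals <- function(x, ...) {
  cat(sprintf(
    "FAME class totals (wt%%): SFA %.1f  MUFA %.1f  PUFA %.1f  UFA %.0f\n",
    x$sfa, x$mufa, x$pufa, x$ufa))
  if (x$ratio_defined) {
    cat(sprintf("SFA/UFA ratio: %.2f\n", x$sfa_ufa_ratio))
  } else {
    cat("SFA/UFA ratio undefined (no unsaturated species)\n")
  }
  invisible(x)
}

#' Read FAME profiles from CSV
#'
#' Expects a header `species,<sample_id_1>,<sample_id_2>,...` with one row
#' per shorthand token.  Cells that are empty or `"ND"` (not detected) mean
#' the species is absent from that sample and it is omitted from the profile
#' — an ND is never turned into a zero-weight species.
#'
#' @param path CSV file path.
#' @param media Optional named character vector mapping sample id to growth
#'   medium label.
#' @return Named list of `fame_profile`, one per sample column.
#' @export
read_fame_csv <- function(path, media = NULL) {
  if (!file.exists(path)) {
    .fame_error(sprintf("FAME CSV not found: %s", path), "famefuel_io_error")
  }
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(tab) < 2L || names(tab)[1] != "species") {
    .fame_error(sprintf("%s: expected header 'species,<sample>,...'", path),
                "famefuel_io_error")
  }
  if (anyDuplicated(tab$species)) {
    .fame_error(sprintf("%s: duplicate species rows: %s", path,
                        paste(unique(tab$species[duplicated(tab$species)]),
                              collapse = ", ")),
                "famefuel_io_error")
  }
  samples <- names(tab)[-1]
  profiles <- lapply(samples, function(sid) {
    cells <- tab[[sid]]
    present <- !(cells %in% c("", "ND", "nd", "NA"))
    vals <- suppressWarnings(as.numeric(cells[present]))
    if (anyNA(vals)) {
      bad <- which(present)[which(is.na(vals))[1]]
      .fame_error(sprintf(
        "%s: non-numeric weight percent '%s' at row %d, column '%s'",
        path, cells[bad], bad, sid), "famefuel_io_error")
    }
    species <- Map(parse_fame_notation, tab$species[present], vals)
    fame_profile(sid, unname(species),
                 medium = if (!is.null(media) && sid %in% names(media))
                   media[[sid]] else sid)
  })
  names(profiles) <- samples
  profiles
}

#' Write FAME profiles to CSV
#'
#' Inverse of [read_fame_csv()]: species are written in order of first
#' appearance across profiles, with `"ND"` for species absent from a sample,
#' so that `read_fame_csv(write_fame_csv(p))` round-trips.
#'
#' @param profiles Named list of `fame_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fame_csv <- function(profiles, path) {
  stopifnot(length(profiles) > 0)
  # order-preserving merge of the per-profile species sequences, so each
  # profile reads back in its own relative order
  all_species <- profiles[[1]]$species$notation
  for (p in profiles[-1]) {
    pos <- 0L
    for (sp in p$species$notation) {
      at <- match(sp, all_species)
      if (is.na(at)) {
        all_species <- append(all_species, sp, after = pos)
        pos <- pos + 1L
      } else {
        pos <- max(pos, at)
      }
    }
  }
  cols <- lapply(profiles, function(p) {
    idx <- match(all_species, p$species$notation)
    ifelse(is.na(idx), "ND",
           format(p$species$weight_percent[idx], trim = TRUE))
  })
  out <- data.frame(species = all_species, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("species", vapply(profiles, `[[`, "", "sample_id"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export parsed FAME profiles as JSON
#'
#' @param profiles Named list of `fame_profile`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fame_json <- function(profiles, path) {
  payload <- lapply(profiles, function(p) {
    list(sample_id = p$sample_id, medium = p$medium, species = p$species)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Path to the packaged Table 2 FAME fixture
#'
#' FAME compositions (weight percent) of the PW- and BG-11-grown cultures,
#' with ND rows retained.
#'
#' @return File path of `table2_fame.csv` inside the installed package.
#' @export
table2_fame_path <- function() {
  system.file("extdata", "table2_fame.csv", package = "famefuel",
              mustWork = TRUE)
}
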