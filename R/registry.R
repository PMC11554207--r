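#' Species origin categories
#'
#' Every species in a registry is classified as `native`, `non_native`, or
#' `unclassified`.  Unclassified species are kept in the tables but take part
#' in no contamination index and in neither richness nor biomass totals: the
#' indices partition assemblages strictly into native and non-native parts.
#'
#' @format A character vector of the three valid origin labels.
#' @export
origin_levels <- c("native", "non_native", "unclassified")

#' Read a species origin registry
#'
#' Reads a delimited text file mapping species to their origin
#' (native / non-native / unclassified).  Origin strings are lower-cased and
#' trimmed; a few common spellings (`"non-native"`, `"nonnative"`,
#' `"exotic"`, `"alien"`) are normalised to `non_native`.  Any other
#' unrecognised origin (including `"NA"` or an empty field) is mapped to
#' `unclassified` with a warning, so a registry never silently drops a
#' species.
#'
#' @param path Path to a UTF-8 CSV file with header
#'   `species_id,species_name,origin`.
#' @return A tibble with columns `species_id`, `species_name`, `origin`.
#' @seealso [synthetic_species_registry()] to build a registry in code.
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("species_id", "species_name", "origin")
  if (!all(required %in% names(reg))) {
    stop("registry must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  reg <- reg[required]
  if (nrow(reg) == 0) stop("registry is empty", call. = FALSE)
  dup <- reg$species_id[duplicated(reg$species_id)]
  if (length(dup) > 0) {
    stop("duplicate species_id in registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  reg$origin <- normalize_origin(reg$origin)
  as_tibble(reg)
}

normalize_origin <- function(origin) {
  x <- tolower(trimws(as.character(origin)))
  x[x %in% c("non-native", "nonnative", "non native", "exotic", "alien")] <-
    "non_native"
  bad <- !(x %in% origin_levels) | is.na(x)
  if (any(bad)) {
    warning(sum(bad), " unrecognised origin value(s) (",
            paste(unique(origin[bad]), collapse = ", "),
            ") mapped to 'unclassified'", call. = FALSE)
    x[bad] <- "unclassified"
  }
  x
}

#' Generate a synthetic species registry
#'
#' Builds a deterministic, synthetic stand-in for a published floodplain
#' species list: plausible-looking Latin binomials with a fixed census
#' structure.  The default census (85 native, 68 non-native, 4 unclassified;
#' 157 species in total) mirrors the species pool reported for the upper
#' Parana River floodplain long-term monitoring program.  The names are
#' invented, not real taxa: the generator exists so parsing, validation, and
#' census arithmetic can be exercised without the (undeposited) survey data.
#'
#' @param n_native,n_nonnative,n_unclassified Number of species per origin
#'   class.
#' @return A registry tibble (`species_id`, `species_name`, `origin`).
#' @examples
#' reg <- synthetic_species_registry()
#' table(reg$origin)
#' @export
synthetic_species_registry <- function(n_native = 85, n_nonnative = 68,
                                       n_unclassified = 4) {
  stopifnot(n_native >= 0, n_nonnative >= 0, n_unclassified >= 0)
  n <- n_native + n_nonnative + n_unclassified
  stems <- c("Astyan", "Serras", "Pimelo", "Lorica", "Hoplia", "Cichla",
             "Prochilo", "Leporin", "Gymnot", "Trichomy", "Doradi", "Auchen",
             "Parodon", "Acestro", "Rhamdi", "Crenici", "Hypost", "Megalo",
             "Brycon", "Schizo")
  suffix <- c("ax", "almus", "odus", "ichthys", "osoma", "ella", "urus",
              "ops")
  epithet <- c("paranensis", "fluviatilis", "lacustris", "maculatus",
               "fasciatus", "minor", "major", "aureus", "niger", "vittatus",
               "punctatus", "elongatus", "gracilis", "robustus")
  genus <- paste0(rep(stems, length.out = n),
                  suffix[(seq_len(n) - 1L) %/% length(stems) %% length(suffix) + 1L])
  sp <- epithet[(seq_len(n) - 1L) %% length(epithet) + 1L]
  tibble(
    species_id = sprintf("sp%03d", seq_len(n)),
    species_name = paste(genus, sp),
    origin = rep(origin_levels, times = c(n_native, n_nonnative, n_unclassified))
  )
}
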