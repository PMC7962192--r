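# Physicochemical property tables (AAindex) used by the aaindex encoder.

# Accessions of the default 15-property set, bundled from seqinr's copy of
# the AAindex database. Chosen to span the property families practitioners
# reach for: hydropathy/hydrophilicity, polarity, charge, size/volume,
# surface exposure, flexibility, polarizability, mutability and secondary
# structure propensity.
DEFAULT_AAINDEX_IDS <- c(
  "KYTJ820101",  # hydropathy (Kyte-Doolittle)
  "HOPT810101",  # hydrophilicity (Hopp-Woods)
  "GRAR740102",  # polarity (Grantham)
  "ZIMJ680104",  # isoelectric point
  "CHOC760101",  # residue accessible surface area
  "BHAR880101",  # average flexibility index
  "CHAM820101",  # polarizability
  "DAYM780201",  # relative mutability
  "FAUJ880103",  # normalized van der Waals volume
  "JANJ780101",  # average buried area
  "KLEP840101",  # net charge
  "FASG760101",  # molecular weight
  "CHOP780201",  # alpha-helix propensity (Chou-Fasman)
  "RADA880108",  # mean polarity
  "NADH010101"   # hydropathy scale based on self-information values
)

THREE_TO_ONE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
                  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
                  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
                  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Default physicochemical property set
#'
#' Returns the bundled default of 15 AAindex properties as a wide tibble,
#' one row per property with one column per amino-acid letter. The set is
#' a documented, versioned default (the accessions above) and can be
#' replaced by any table read with [read_aaindex()].
#'
#' @return A tibble with columns `property_id`, `description`, then the 20
#'   standard amino-acid letters.
#' @export
default_properties <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  missing <- setdiff(DEFAULT_AAINDEX_IDS, names(aaindex))
  if (length(missing) > 0) {
    abort_fmt("AAindex accession(s) not available: %s",
              paste(missing, collapse = ", "))
  }
  rows <- purrr::map(DEFAULT_AAINDEX_IDS, function(id) {
    entry <- aaindex[[id]]
    vals <- entry$I
    names(vals) <- THREE_TO_ONE[names(vals)]
    vals <- vals[AA20]
    if (anyNA(vals)) abort_fmt("property %s is missing a letter", id)
    c(list(property_id = id, description = entry$D), as.list(vals))
  })
  dplyr::bind_rows(rows)
}

#' Read an AAindex1 flat file
#'
#' Parses the standard AAindex1 record format: `H` lines give the accession,
#' `D` lines the description, and the `I` line is followed by two rows of
#' ten values in the fixed A R N D C Q E G H I / L K M F P S T W Y V order.
#'
#' @param path Path to an AAindex1-format file (one or more records).
#' @return A wide property tibble as from [default_properties()].
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^H ", lines)
  if (length(starts) == 0) abort_fmt("no 'H' records found in %s", path)
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ends <- c(starts[-1] - 1, length(lines))
  rows <- Map(function(s, e) {
    block <- lines[s:e]
    id <- trimws(sub("^H ", "", block[1]))
    d <- grep("^D ", block, value = TRUE)
    desc <- if (length(d) > 0) trimws(sub("^D ", "", d[1])) else ""
    i_at <- grep("^I ", block)
    if (length(i_at) == 0 || i_at[1] + 2 > length(block)) {
      abort_fmt("record %s has no complete 'I' value block", id)
    }
    parse_row <- function(ln) {
      suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    }
    v1 <- parse_row(block[i_at[1] + 1])
    v2 <- parse_row(block[i_at[1] + 2])
    if (length(v1) != 10 || length(v2) != 10 || anyNA(c(v1, v2))) {
      abort_fmt("property %s is missing a letter (incomplete 'I' block)", id)
    }
    vals <- c(stats::setNames(v1, order1), stats::setNames(v2, order2))[AA20]
    c(list(property_id = id, description = desc), as.list(vals))
  }, starts, ends)
  dplyr::bind_rows(rows)
}

# Property tibble -> 21 x P numeric lookup matrix (rows AA20 + gap), values
# z-score standardized across the 20 letters; gap and 'X' contribute 0 (the
# standardized mean).
property_lookup <- function(properties, standardize = TRUE) {
  stopifnot(all(AA20 %in% names(properties)))
  V <- t(as.matrix(properties[, AA20]))  # 20 x P
  colnames(V) <- properties$property_id
  if (standardize) {
    V <- scale(V)
    V[, attr(V, "scaled:scale") == 0] <- 0
  }
  rbind(V, matrix(0, nrow = 1, ncol = ncol(V), dimnames = list(GAP, NULL)))
}
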