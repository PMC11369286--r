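# Lipid shorthand parsing and PUFA-tail classification of phospholipids.

lipidTailCounts <- c(PC = 2L, PE = 2L, PG = 2L, PS = 2L, PI = 2L, PA = 2L,
                     SM = 2L, DAG = 2L, TAG = 3L, MAG = 1L, CE = 1L,
                     LPC = 1L, LPE = 1L)

#' Parse lipid shorthand names
#'
#' Grammar: `CLASS [O-|P-]C1:D1[_|/]C2:D2[...]` — a headgroup class
#' token, an optional ether-linkage prefix (`O-` plasmanyl, `P-`
#' plasmenyl; both set the ether flag, the distinction is kept as
#' metadata), and one tail token `carbons:doubleBonds` per acyl chain.
#' `/` marks known sn-positions, `_` unknown (recorded, not used for
#' classification). A single tail token for a multi-tail class (e.g.
#' `TAG 52:2`) is sum resolution: only totals are known, individual tails
#' unresolved.
#'
#' @param names character vector of shorthand names.
#' @return data.frame with one row per name: `name`, `class`, `ether`,
#'   `etherType`, `resolution` (`full`/`sum`), `separator`, `nTails`, and
#'   a list-column `tails` of 2-column matrices (`carbons`,
#'   `doubleBonds`).
#' @examples
#' parseLipid(c("PG 18:2_20:4", "PC O-16:0/20:4", "TAG 52:2"))
#' @export
parseLipid <- function(names) {
  stopifnot(is.character(names), all(nzchar(names)))
  one <- function(nm) {
    m <- regexec("^([A-Za-z][A-Za-z0-9]*) (O-|P-)?(\\d+:\\d+([_/]\\d+:\\d+)*)$",
                 nm)[[1L]]
    if (m[1L] == -1L) {
      cls <- sub(" .*$", "", nm)
      if (!cls %in% names(lipidTailCounts))
        stop("unknown class token '", cls, "' at position 1 in '", nm, "'")
      stop("malformed tail at position ", nchar(cls) + 2L, " in '", nm, "'")
    }
    parts <- regmatches(nm, list(m))[[1L]]
    cls <- parts[2L]
    if (!cls %in% names(lipidTailCounts))
      stop("unknown class token '", cls, "' at position 1 in '", nm, "'")
    etherType <- if (nzchar(parts[3L])) substr(parts[3L], 1L, 1L) else NA_character_
    tailStr <- parts[4L]
    sep <- if (grepl("/", tailStr, fixed = TRUE)) "/" else "_"
    tokens <- strsplit(tailStr, "[_/]")[[1L]]
    tails <- do.call(rbind, lapply(tokens, function(t) {
      v <- as.integer(strsplit(t, ":", fixed = TRUE)[[1L]])
      if (v[1L] < 2L * v[2L] + 1L)
        stop("impossible tail ", t, " in '", nm,
             "' (carbons < 2 * double bonds + 1)")
      v
    }))
    colnames(tails) <- c("carbons", "doubleBonds")
    expected <- lipidTailCounts[[cls]]
    res <- if (length(tokens) == expected) "full"
    else if (length(tokens) == 1L && expected > 1L) "sum"
    else stop("expected ", expected, " tail(s) for class ", cls,
              " in '", nm, "', got ", length(tokens))
    list(class = cls, ether = !is.na(etherType), etherType = etherType,
         resolution = res, separator = sep, nTails = nrow(tails),
         tails = tails)
  }
  parsed <- lapply(names, one)
  out <- data.frame(
    name = names,
    class = vapply(parsed, `[[`, character(1), "class"),
    ether = vapply(parsed, `[[`, logical(1), "ether"),
    etherType = vapply(parsed, `[[`, character(1), "etherType"),
    resolution = vapply(parsed, `[[`, character(1), "resolution"),
    separator = vapply(parsed, `[[`, character(1), "separator"),
    nTails = vapply(parsed, `[[`, integer(1), "nTails"))
  out$tails <- lapply(parsed, `[[`, "tails")
  out
}

#' Format parsed lipids back to canonical shorthand
#'
#' Inverse of [parseLipid()]: `format(parse(x))` is the canonical form of
#' `x`, and `parse(format(s))` reproduces `s`.
#'
#' @param parsed data.frame from [parseLipid()].
#' @return character vector of shorthand names.
#' @export
formatLipid <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    tails <- parsed$tails[[i]]
    pre <- if (parsed$ether[i]) paste0(parsed$etherType[i], "-") else ""
    paste0(parsed$class[i], " ", pre,
           paste(sprintf("%d:%d", tails[, 1L], tails[, 2L]),
                 collapse = parsed$separator[i]))
  }, character(1))
}

#' Classify species by PUFA tail content
#'
#' A PUFA tail carries at least 2 double bonds. Fully resolved species
#' are classified `PUFA<k>` where k is the number of PUFA tails; ether
#' species with at least one PUFA tail are additionally flagged `ePUFA`.
#' Sum-resolution species are `unresolved`. Classification does not
#' depend on tail order or sn-position.
#'
#' @param parsed data.frame from [parseLipid()].
#' @return the input with added columns `category` and `ePufa`.
#' @export
classifyPufa <- function(parsed) {
  nPufa <- vapply(seq_len(nrow(parsed)), function(i)
    sum(parsed$tails[[i]][, "doubleBonds"] >= 2L), integer(1))
  parsed$category <- ifelse(parsed$resolution == "sum", "unresolved",
                            paste0("PUFA", nPufa))
  parsed$ePufa <- parsed$ether & nPufa >= 1L & parsed$resolution == "full"
  parsed
}

#' Abundance-weighted PUFA class fractions per headgroup class
#'
#' Percentage of each headgroup class's abundance in the PUFA0 / PUFA1 /
#' PUFA2 (/ PUFA3 for triacylglycerols) categories; the overlapping
#' ether-PUFA flag is normalized separately against the same resolved
#' denominator. Sum-resolution species are excluded from the denominator
#' and their count reported; classes with all-zero abundance are omitted
#' with a warning.
#'
#' @param species data.frame with columns `name` and `abundance`
#'   (abundances >= 0), or an already parsed+classified table carrying an
#'   `abundance` column.
#' @return data.frame with one row per headgroup class: percentage
#'   columns `PUFA0`..`PUFA3` (summing to 100 per row), `ePUFA`, and
#'   `unresolved` (species count excluded from the denominator).
#' @examples
#' tab <- data.frame(name = c("PG 18:2_20:4", "PG 16:0_18:1"),
#'                   abundance = c(1, 3))
#' classFractions(tab)   # PG-PUFA2 = 25%
#' @export
classFractions <- function(species) {
  stopifnot("abundance" %in% names(species))
  if (any(species$abundance < 0)) stop("abundances must be >= 0")
  parsed <- if ("category" %in% names(species)) species
  else classifyPufa(cbind(parseLipid(species$name),
                          abundance = species$abundance))
  cats <- paste0("PUFA", 0:3)
  out <- list()
  for (cl in unique(parsed$class)) {
    rows <- parsed[parsed$class == cl, ]
    unres <- sum(rows$category == "unresolved")
    rows <- rows[rows$category != "unresolved", ]
    tot <- sum(rows$abundance)
    if (nrow(rows) == 0L || tot == 0) {
      warning("class ", cl, " has no resolved abundance; omitted")
      next
    }
    pct <- vapply(cats, function(ct)
      100 * sum(rows$abundance[rows$category == ct]) / tot, numeric(1))
    out[[cl]] <- data.frame(class = cl, t(pct),
                            ePUFA = 100 * sum(rows$abundance[rows$ePufa]) / tot,
                            unresolved = unres)
  }
  if (length(out) && any(parsed$category == "unresolved"))
    message(sum(parsed$category == "unresolved"),
            " sum-resolution species excluded from denominators")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
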