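## Pedigree construction, validation and IO.

#' Construct a validated Pedigree
#'
#' Resolves parent identifiers, checks structural validity and returns the
#' pedigree in a deterministic topological order (by ancestral depth, then
#' id), so that the same set of rows always yields the same object whatever
#' their input order.
#'
#' @param id character vector of individual identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or the
#'   `unknown` sentinel mark an unknown parent.
#' @param birthDate optional vector coercible with [parseDates()]; `NA`
#'   allowed.
#' @param sex optional character vector (`male`/`female`/`dummy`/`unknown`);
#'   defaults to `"unknown"`. Common abbreviations (`M`/`F`, `1`/`2`) are
#'   accepted.
#' @param unknown sentinel string(s) encoding an unknown parent
#'   (default `"0"`).
#' @param addMissingFounders if `TRUE`, parent ids without their own record
#'   are inserted as founders; if `FALSE` (default) they are an error.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
#'                 dam = c(NA, NA, "B"), sex = c("male", "female", "unknown"))
#' founders(ped)
#' @export
Pedigree <- function(id, sire, dam, birthDate = NULL, sex = NULL,
                     unknown = "0", addMissingFounders = FALSE) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyNA(id) || any(!nzchar(id))) stop("ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicated id '", dup[1L], "'")
  blank <- function(p) is.na(p) | !nzchar(p) | p %in% unknown
  sire[blank(sire)] <- NA_character_
  dam[blank(dam)] <- NA_character_

  missing <- setdiff(c(sire, dam), c(id, NA))
  if (length(missing)) {
    if (!addMissingFounders)
      stop("parent(s) without a pedigree record: ",
           paste(head(missing, 5L), collapse = ", "),
           " (set addMissingFounders = TRUE to insert them as founders)")
    k <- length(missing)
    id <- c(id, missing)
    sire <- c(sire, rep(NA_character_, k))
    dam <- c(dam, rep(NA_character_, k))
    if (!is.null(birthDate)) birthDate <- c(parseDates(birthDate),
                                            rep(as.Date(NA), k))
    if (!is.null(sex)) sex <- c(as.character(sex), rep(NA_character_, k))
  }
  n <- length(id)
  bd <- if (is.null(birthDate)) as.Date(rep(NA, n)) else parseDates(birthDate)
  sx <- normalizeSex(if (is.null(sex)) rep("unknown", n) else sex)
  if (length(bd) != n || length(sx) != n)
    stop("birthDate and sex must have one entry per individual")

  si <- match(sire, id)
  di <- match(dam, id)
  self <- which(si == seq_len(n) | di == seq_len(n))
  if (length(self))
    stop("cycle detected in pedigree involving individual '", id[self[1L]],
         "' (it is its own parent)")

  depth <- pedigreeDepth(si, di, id)
  ord <- order(depth, id, method = "radix")
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  toIdx <- function(p) ifelse(is.na(p), 0L, pos[p])
  obj <- new("Pedigree",
             id = id[ord],
             sire = as.integer(toIdx(si)[ord]),
             dam = as.integer(toIdx(di)[ord]),
             birthDate = bd[ord],
             sex = sx[ord])
  validObject(obj)
  obj
}

# ancestral depth per individual; errors (naming an individual) on cycles
pedigreeDepth <- function(si, di, id) {
  n <- length(id)
  depth <- ifelse(is.na(si) & is.na(di), 0L, NA_integer_)
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ds <- ifelse(is.na(si[todo]), -1L, depth[si[todo]])
    dd <- ifelse(is.na(di[todo]), -1L, depth[di[todo]])
    ready <- !is.na(ds) & !is.na(dd)
    if (!any(ready))
      stop("cycle detected in pedigree involving individual '",
           id[todo[1L]], "'")
    depth[todo[ready]] <- pmax(ds[ready], dd[ready]) + 1L
  }
  depth
}

normalizeSex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[is.na(sex) | sex == ""] <- "unknown"
  map <- c(m = "male", male = "male", "1" = "male",
           f = "female", female = "female", "2" = "female",
           d = "dummy", dummy = "dummy", unknown = "unknown",
           u = "unknown", "0" = "unknown")
  out <- unname(map[sex])
  if (anyNA(out)) stop("unrecognised sex code: ",
                       paste(unique(sex[is.na(out)]), collapse = ", "))
  out
}

#' Parse dates, allowing month precision
#'
#' ISO-8601 dates (`"1997-06-15"`) are parsed as-is; month-precision values
#' (`"1997-06"`) get day 15, because period splits in this workflow are at
#' month level.
#'
#' @param x character or `Date` vector.
#' @return a `Date` vector.
#' @export
parseDates <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  monthOnly <- !is.na(x) & grepl("^\\d{4}-\\d{1,2}$", x)
  x[monthOnly] <- paste0(x[monthOnly], "-15")
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("unparseable date(s): ",
                     paste(head(unique(x[bad]), 5L), collapse = ", "))
  out
}

#' Read a pedigree from CSV
#'
#' @param path CSV file with a header.
#' @param columns named character vector mapping the roles `id`, `sire`,
#'   `dam`, and optionally `birthDate` and `sex`, to column names in the
#'   file.
#' @param unknown sentinel value(s) encoding unknown parents (default `"0"`;
#'   empty cells always count as unknown).
#' @param addMissingFounders insert referenced-but-absent parents as founders
#'   instead of failing.
#' @return a [Pedigree-class] object; the number of individuals equals the
#'   number of data rows (plus inserted founders, if requested).
#' @export
readPedigree <- function(path,
                         columns = c(id = "id", sire = "sire", dam = "dam",
                                     birthDate = "birth_date", sex = "sex"),
                         unknown = "0", addMissingFounders = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (role in c("id", "sire", "dam"))
    if (!columns[[role]] %in% names(df))
      stop("column '", columns[[role]], "' (", role, ") not found in ", path)
  getCol <- function(role) {
    cn <- if (role %in% names(columns)) columns[[role]] else role
    if (cn %in% names(df)) df[[cn]] else NULL
  }
  Pedigree(id = getCol("id"), sire = getCol("sire"), dam = getCol("dam"),
           birthDate = getCol("birthDate"), sex = getCol("sex"),
           unknown = unknown, addMissingFounders = addMissingFounders)
}

#' Deterministic litter-dummy identifier for a mating pair
#'
#' @param dam,sire parent identifiers.
#' @return character id, unique per (dam, sire) pair.
#' @export
litterDummyId <- function(dam, sire) {
  if (!length(dam)) return(character(0))
  paste0("litter:", dam, "x", sire)
}

#' Append one dummy progeny per unique mating pair
#'
#' Litters have no pedigree record of their own, so one dummy progeny is
#' created per unique (dam, sire) combination; repeated kindlings of the same
#' pair share the same dummy, and the dummy carries the litter-level
#' inbreeding coefficients.
#'
#' @param ped a [Pedigree-class].
#' @param dam,sire character vectors (recycled together) of mating pairs; all
#'   must exist in `ped`.
#' @return a re-validated `Pedigree` containing the dummies (sex `"dummy"`,
#'   ids from [litterDummyId()]).
#' @export
addDummyProgenies <- function(ped, dam, sire) {
  stopifnot(is(ped, "Pedigree"), length(dam) == length(sire))
  if (!length(dam)) return(ped)
  dam <- as.character(dam)
  sire <- as.character(sire)
  bad <- setdiff(c(dam, sire), ped@id)
  if (length(bad)) stop("unknown dam/sire id(s): ",
                        paste(head(bad, 5L), collapse = ", "))
  pairs <- unique(data.frame(dam = dam, sire = sire,
                             stringsAsFactors = FALSE))
  did <- litterDummyId(pairs$dam, pairs$sire)
  clash <- intersect(did, ped@id)
  if (length(clash)) stop("dummy id collides with an existing id: ",
                          clash[1L])
  Pedigree(id = c(ped@id, did),
           sire = c(idOrNA(ped, ped@sire), pairs$sire),
           dam = c(idOrNA(ped, ped@dam), pairs$dam),
           birthDate = c(ped@birthDate, as.Date(rep(NA, nrow(pairs)))),
           sex = c(ped@sex, rep("dummy", nrow(pairs))))
}

idOrNA <- function(ped, idx) {
  out <- rep(NA_character_, length(idx))
  out[idx > 0L] <- ped@id[idx[idx > 0L]]
  out
}

## ---- accessors & methods ----------------------------------------------

#' @rdname Pedigree-class
#' @export
setMethod("pedIds", "Pedigree", function(x) x@id)

#' @rdname Pedigree-class
#' @export
setMethod("pedSires", "Pedigree", function(x)
  setNames(idOrNA(x, x@sire), x@id))

#' @rdname Pedigree-class
#' @export
setMethod("pedDams", "Pedigree", function(x)
  setNames(idOrNA(x, x@dam), x@id))

#' @rdname Pedigree-class
#' @export
setMethod("birthDates", "Pedigree", function(x) setNames(x@birthDate, x@id))

#' @rdname Pedigree-class
#' @export
setMethod("pedSex", "Pedigree", function(x) setNames(x@sex, x@id))

#' @rdname Pedigree-class
#' @export
setMethod("isFounder", "Pedigree", function(x)
  setNames(x@sire == 0L & x@dam == 0L, x@id))

#' @rdname Pedigree-class
#' @export
setMethod("founders", "Pedigree", function(x) x@id[x@sire == 0L & x@dam == 0L])

#' @rdname Pedigree-class
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat("Pedigree with", n, "individuals (",
      sum(object@sire == 0L & object@dam == 0L), "founders,",
      sum(object@sex == "dummy"), "dummy progenies )\n")
  if (n) {
    rng <- range(object@birthDate, na.rm = TRUE)
    if (all(is.finite(rng)))
      cat("  birth dates:", format(rng[1L]), "to", format(rng[2L]), "\n")
  }
})

#' Export a pedigree as a data.frame
#'
#' @param x a [Pedigree-class].
#' @param ... unused.
#' @return data.frame with columns `id`, `sire`, `dam`, `birth_date`, `sex`
#'   in topological order (unknown parents as `NA`).
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(id = x@id,
             sire = idOrNA(x, x@sire),
             dam = idOrNA(x, x@dam),
             birth_date = x@birthDate,
             sex = x@sex,
             stringsAsFactors = FALSE)
})
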