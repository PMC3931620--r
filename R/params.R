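## Loading, validating, writing and temperature-rescaling energy parameters.

.T_REF <- 310.15

.builtinParamFile <- function(name) {
  file <- switch(name,
    turner99 = , turner1999 = "turner1999.json",
    turner04 = , turner2004 = "turner2004.json",
    NULL)
  if (is.null(file)) return(NULL)
  system.file("extdata", file, package = "TripletFold", mustWork = TRUE)
}

.numCheck <- function(x, key) {
  if (is.null(x)) stop("parameter file is missing key '", key, "'")
  v <- suppressWarnings(as.numeric(unlist(x)))
  if (any(is.na(v) != is.na(unlist(x))))
    stop("non-numeric value under key '", key, "'")
  v
}

.lenTable <- function(doc, key, minSize) {
  dg <- .numCheck(doc[[key]][["dG37"]], paste0(key, ".dG37"))
  dh <- .numCheck(doc[[key]][["dH"]], paste0(key, ".dH"))
  if (length(dg) != 30L || length(dh) != 30L)
    stop("key '", key, "' must tabulate loop sizes 1..30")
  if (any(is.na(dg[minSize:30])))
    stop("key '", key, "' has an undefined cell at a realizable size")
  ## a finite dG37 with an unreported enthalpy is treated as purely entropic
  dh[is.na(dh) & !is.na(dg)] <- 0
  list(dG = dg, dH = dh)
}

#' Load an energy parameter set
#'
#' Reads a parameter JSON document (see the package vignette for the schema)
#' or one of the shipped sets \code{"turner99"} / \code{"turner04"},
#' transcriptions of the published Turner 1999 and Turner 2004
#' nearest-neighbor tables.
#'
#' @param source set name (\code{"turner99"}, \code{"turner04"}) or a file
#'   path (optionally prefixed \code{"file:"})
#' @return An \linkS4class{EnergyParams} object.
#' @examples
#' p <- loadParameters("turner99")
#' p
#' @export
loadParameters <- function(source = "turner99") {
  if (is(source, "EnergyParams")) return(source)
  stopifnot(is.character(source), length(source) == 1L)
  path <- .builtinParamFile(source)
  if (is.null(path)) {
    path <- sub("^file:", "", source)
    if (!file.exists(path)) stop("unknown parameter set or missing file: ", source)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("stack", "hairpin", "bulge", "internal", "multiloop",
                "terminal_nongc"))
    if (is.null(doc[[key]])) stop("parameter file is missing key '", key, "'")

  po <- doc[["pair_order"]]
  if (is.null(po)) po <- pairTypes()
  if (!identical(sort(po), sort(pairTypes())))
    stop("pair_order must be a permutation of ", paste(pairTypes(), collapse = ","))
  reorder <- match(pairTypes(), po)

  ## jsonlite materializes the nested arrays as a 6x6 matrix directly
  readStackM <- function(key) {
    raw <- doc[["stack"]][[key]]
    if (is.null(raw)) stop("parameter file is missing key 'stack.", key, "'")
    m <- as.matrix(raw)
    if (!all(dim(m) == c(6L, 6L))) stop("stack.", key, " must be 6x6")
    storage.mode(m) <- "numeric"
    if (any(is.na(m))) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("parameter file is missing stack.%s cell (%s, %s)",
                   key, po[bad[1]], po[bad[2]]))
    }
    m <- m[reorder, reorder, drop = FALSE]
    dimnames(m) <- list(pairTypes(), pairTypes())
    m
  }

  hp <- .lenTable(doc, "hairpin", 3L)
  bu <- .lenTable(doc, "bulge", 1L)
  il <- .lenTable(doc, "internal", 2L)
  ml <- doc[["multiloop"]]
  mlv <- vapply(c("a", "b", "c", "a_dH", "b_dH", "c_dH"), function(k)
    .numCheck(ml[[k]], paste0("multiloop.", k)), numeric(1))
  tn <- doc[["terminal_nongc"]]
  tnv <- c(dG37 = .numCheck(tn[["dG37"]], "terminal_nongc.dG37"),
           dH = .numCheck(tn[["dH"]], "terminal_nongc.dH"))
  lxc <- if (is.null(doc[["lxc"]])) 1.07856 else .numCheck(doc[["lxc"]], "lxc")

  tl <- doc[["tetraloop"]]
  tdg <- tdh <- numeric(0)
  if (!is.null(tl) && length(tl[["dG37"]])) {
    tdg <- unlist(tl[["dG37"]]); tdh <- unlist(tl[["dH"]])
    tdh <- tdh[names(tdg)]
  }

  name <- if (is.null(doc[["name"]])) basename(path) else doc[["name"]]
  new("EnergyParams", name = name,
      stackDG = readStackM("dG37"), stackDH = readStackM("dH"),
      hairpinDG = hp$dG, hairpinDH = hp$dH,
      bulgeDG = bu$dG, bulgeDH = bu$dH,
      internalDG = il$dG, internalDH = il$dH,
      multiloop = mlv, terminalNonGC = tnv, lxc = lxc,
      tetraloopDG = tdg, tetraloopDH = tdh)
}

#' Write an energy parameter set to a JSON file
#'
#' Inverse of \code{\link{loadParameters}}: the written document reloads
#' cell-for-cell.
#'
#' @param params an \linkS4class{EnergyParams}
#' @param path output file
#' @return \code{path}, invisibly.
#' @export
writeParameters <- function(params, path) {
  stopifnot(is(params, "EnergyParams"))
  naNull <- function(v) lapply(as.numeric(v), function(x) if (is.na(x)) NULL else x)
  doc <- list(
    name = params@name,
    reference_temperature = .T_REF,
    pair_order = pairTypes(),
    stack = list(dG37 = unname(params@stackDG), dH = unname(params@stackDH)),
    hairpin = list(dG37 = naNull(params@hairpinDG), dH = naNull(params@hairpinDH)),
    bulge = list(dG37 = naNull(params@bulgeDG), dH = naNull(params@bulgeDH)),
    internal = list(dG37 = naNull(params@internalDG), dH = naNull(params@internalDH)),
    multiloop = as.list(params@multiloop),
    terminal_nongc = as.list(params@terminalNonGC),
    lxc = params@lxc,
    tetraloop = list(dG37 = as.list(params@tetraloopDG),
                     dH = as.list(params@tetraloopDH))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rescale a free energy to another temperature
#'
#' Linear enthalpy/entropy decomposition anchored at the 310.15 K reference:
#' dG(T) = dH - T (dH - dG37) / 310.15.
#'
#' @param dG37 free energy at 310.15 K (kcal/mol); vectorized
#' @param dH enthalpy (kcal/mol)
#' @param temperature target temperature in Kelvin
#' @return dG at \code{temperature}, same shape as \code{dG37}.
#' @examples
#' rescaleToTemperature(-2, -10, 310.15)  # exact at the reference
#' @export
rescaleToTemperature <- function(dG37, dH, temperature) {
  stopifnot(temperature > 0)
  dH - temperature * (dH - dG37) / .T_REF
}

## loop energy vector for sizes 1..nmax at temperature T, with
## Jacobson-Stockmayer log extrapolation beyond size 30 (lxc at 37 C,
## rescaled with the size-30 enthalpy); undefined sizes become +Inf
.loopVector <- function(dg, dh, temperature, nmax, lxc) {
  sizes <- seq_len(max(nmax, 30L))
  g37 <- c(dg, rep(NA_real_, length(sizes) - 30L))
  h <- c(dh, rep(NA_real_, length(sizes) - 30L))
  if (length(sizes) > 30L) {
    ext <- 31L:length(sizes)
    g37[ext] <- dg[30L] + lxc * log(ext / 30)
    h[ext] <- dh[30L]
  }
  e <- rescaleToTemperature(g37, ifelse(is.na(h), 0, h), temperature)
  e[is.na(g37)] <- Inf
  e[seq_len(nmax)]
}

.terminalTau <- function(params, config) {
  if (!config@useTerminalNonGC) return(rep(0, 6))
  p <- rescaleToTemperature(params@terminalNonGC[["dG37"]],
                            params@terminalNonGC[["dH"]], config@temperature)
  ## penalty on every closing pair that is not GC or CG
  ifelse(pairTypes() %in% c("GC", "CG"), 0, p)
}

#' Loop free energies
#'
#' Accessors evaluating single loop terms at the configured temperature,
#' with the same conventions the folding engine uses.  \code{hairpinEnergy}
#' includes the gated terminal non-GC penalty (and tetraloop bonus when
#' enabled); \code{bulgeEnergy} and \code{internalEnergy} include the
#' closing-pair penalties for loops of total size >= 2 (a size-1 bulge is
#' treated as part of a continuing helix, so only the length penalty is
#' returned and the flanking stack is added by the caller).
#'
#' @param seq RNA sequence
#' @param i,j outer closing pair (1-based, i < j)
#' @param k,l inner pair for two-pair loops (i < k < l < j)
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @return energy in kcal/mol
#' @examples
#' hairpinEnergy("GAAAC", 1, 5, loadParameters("turner99"), modelConfig())
#' @export
hairpinEnergy <- function(seq, i, j, params, config = modelConfig()) {
  params <- loadParameters(params)
  seq <- normalizeSequence(seq)
  s <- strsplit(seq, "")[[1]]
  tp <- .pairTypeCode(s[i], s[j])
  if (is.na(tp)) stop("closing pair (", i, ", ", j, ") is not canonical")
  size <- j - i - 1L
  if (size < config@theta)
    stop("hairpin size ", size, " is below theta = ", config@theta)
  hp <- .loopVector(params@hairpinDG, params@hairpinDH, config@temperature,
                    max(size, 30L), params@lxc)
  e <- hp[size] + .terminalTau(params, config)[tp]
  if (config@useTetraloop && size == 4L) {
    key <- paste(s[i:j], collapse = "")
    if (key %in% names(params@tetraloopDG))
      e <- e + rescaleToTemperature(params@tetraloopDG[[key]],
                                    params@tetraloopDH[[key]],
                                    config@temperature)
  }
  unname(e)
}

#' @rdname hairpinEnergy
#' @export
bulgeEnergy <- function(seq, i, j, k, l, params, config = modelConfig()) {
  params <- loadParameters(params)
  seq <- normalizeSequence(seq)
  s <- strsplit(seq, "")[[1]]
  if (is.na(.pairTypeCode(s[i], s[j])) || is.na(.pairTypeCode(s[k], s[l])))
    stop("both pairs of a bulge must be canonical")
  if (!(i < k && l < j)) stop("need i < k < l < j")
  n1 <- k - i - 1L; n2 <- j - l - 1L
  if (min(n1, n2) != 0L || max(n1, n2) == 0L)
    stop("a bulge has unpaired bases on exactly one side")
  size <- n1 + n2
  bu <- .loopVector(params@bulgeDG, params@bulgeDH, config@temperature,
                    max(size, 30L), params@lxc)
  tau <- .terminalTau(params, config)
  e <- bu[size]
  if (size >= 2L)
    e <- e + tau[.pairTypeCode(s[i], s[j])] + tau[.pairTypeCode(s[k], s[l])]
  unname(e)
}

#' @rdname hairpinEnergy
#' @export
internalEnergy <- function(seq, i, j, k, l, params, config = modelConfig()) {
  params <- loadParameters(params)
  seq <- normalizeSequence(seq)
  s <- strsplit(seq, "")[[1]]
  if (is.na(.pairTypeCode(s[i], s[j])) || is.na(.pairTypeCode(s[k], s[l])))
    stop("both pairs of an internal loop must be canonical")
  n1 <- k - i - 1L; n2 <- j - l - 1L
  if (min(n1, n2) < 1L) stop("an internal loop has unpaired bases on both sides")
  size <- n1 + n2
  il <- .loopVector(params@internalDG, params@internalDH, config@temperature,
                    max(size, 30L), params@lxc)
  tau <- .terminalTau(params, config)
  unname(il[size] + tau[.pairTypeCode(s[i], s[j])] + tau[.pairTypeCode(s[k], s[l])])
}

#' Affine multiloop energy
#'
#' a + b m + c u for a multiloop with m branching helices (the closing pair
#' included) and u unpaired bases, at the configured temperature.
#'
#' @param m number of branches including the closing pair
#' @param u number of unpaired bases in the loop
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @return energy in kcal/mol
#' @examples
#' multiloopEnergy(3, 4, loadParameters("turner99"))
#' @export
multiloopEnergy <- function(m, u, params, config = modelConfig()) {
  params <- loadParameters(params)
  ml <- params@multiloop
  T <- config@temperature
  a <- rescaleToTemperature(ml[["a"]], ml[["a_dH"]], T)
  b <- rescaleToTemperature(ml[["b"]], ml[["b_dH"]], T)
  cc <- rescaleToTemperature(ml[["c"]], ml[["c_dH"]], T)
  a + b * m + cc * u
}

#' Stacking free energy of two adjacent pairs
#'
#' @param outer,inner pair-type codes (see \code{\link{pairTypes}})
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig} (sets the temperature)
#' @return stack energy in kcal/mol at the configured temperature
#' @examples
#' stackEnergy("GC", "CG", "turner99")
#' @export
stackEnergy <- function(outer, inner, params, config = modelConfig()) {
  params <- loadParameters(params)
  st <- rescaleToTemperature(params@stackDG, params@stackDH, config@temperature)
  st[outer, inner]
}
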