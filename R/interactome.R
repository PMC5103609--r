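#' The three interactome evaluation indices, both directions
#'
#' Given the normalised expression of a ligand gene in cancer (L_C) and
#' stroma (L_S) and of a receptor gene in cancer (R_C) and stroma (R_S),
#' computes for the cancer-to-stroma direction the ligand dependency
#' X = L_C / (L_C + L_S), the receptor dependency Y = R_S / (R_C + R_S) and
#' the signal strength Z = sqrt(L_C * R_S), and the stroma-to-cancer
#' counterparts X = L_S / (L_C + L_S), Y = R_C / (R_C + R_S),
#' Z = sqrt(L_S * R_C). When a denominator is zero the dependency is
#' undefined (NA) in both directions; Z is always computed.
#'
#' @param LC,LS,RC,RS Nonnegative numeric vectors (recycled to a common
#'   length).
#' @return data.frame with columns X_CS, Y_CS, Z_CS, X_SC, Y_SC, Z_SC.
#' @examples
#' computeIndices(4, 12, 9, 16)   # X_CS 0.25, Y_CS 0.64, Z_CS 8
#' @export
computeIndices <- function(LC, LS, RC, RS) {
    n <- max(length(LC), length(LS), length(RC), length(RS))
    LC <- rep_len(LC, n); LS <- rep_len(LS, n)
    RC <- rep_len(RC, n); RS <- rep_len(RS, n)
    if (any(c(LC, LS, RC, RS) < 0))
        stop("expression levels must be nonnegative")
    lsum <- LC + LS
    rsum <- RC + RS
    data.frame(
        X_CS = ifelse(lsum > 0, LC / lsum, NA_real_),
        Y_CS = ifelse(rsum > 0, RS / rsum, NA_real_),
        Z_CS = sqrt(LC * RS),
        X_SC = ifelse(lsum > 0, LS / lsum, NA_real_),
        Y_SC = ifelse(rsum > 0, RC / rsum, NA_real_),
        Z_SC = sqrt(LS * RC)
    )
}

#' Classify a dependency zone
#'
#' Quadrant of the (X, Y) unit square at the 0.5 boundary, boundary
#' inclusive for "strong": zone 1 (mutually dependent) X >= 0.5 and
#' Y >= 0.5; zone 2 X >= 0.5, Y < 0.5; zone 3 X < 0.5, Y >= 0.5; zone 4
#' both < 0.5. Undefined inputs give NA (unclassified).
#'
#' @param X,Y Dependency indices in [0,1], NA when undefined.
#' @return Integer vector of zones 1-4, NA where unclassified.
#' @export
classifyZone <- function(X, Y) {
    z <- ifelse(X >= 0.5,
                ifelse(Y >= 0.5, 1L, 2L),
                ifelse(Y >= 0.5, 3L, 4L))
    z[is.na(X) | is.na(Y)] <- NA_integer_
    as.integer(z)
}

#' Zone label ("CS1", "SC3", ...)
#' @param direction "CS" or "SC" vector.
#' @param zone Integer zone vector.
#' @return Character labels, NA where zone is NA.
#' @export
zoneLabel <- function(direction, zone)
    ifelse(is.na(zone), NA_character_, paste0(direction, zone))

#' Score every interaction of the database
#'
#' Joins the ligand-receptor database with the per-species normalised
#' expression (mouse expression already collapsed onto human gene ids, see
#' \code{\link{collapseMouseHomologs}}) and computes the three indices in
#' both signalling directions. Genes absent from an expression vector
#' contribute zero expression.
#'
#' @param db data.frame from \code{\link{loadInteractionDB}}.
#' @param humanExpr Named numeric vector, human gene id -> normalised copies.
#' @param mouseExpr Named numeric vector keyed by human gene id (homolog
#'   collapsed).
#' @return An \linkS4class{InteractionProfile}.
#' @export
computeInteractionScores <- function(db, humanExpr, mouseExpr) {
    getv <- function(v, g) {
        out <- unname(v[toupper(g)])
        out[is.na(out)] <- 0
        out
    }
    names(humanExpr) <- toupper(names(humanExpr))
    names(mouseExpr) <- toupper(names(mouseExpr))
    LC <- getv(humanExpr, db$ligand)
    LS <- getv(mouseExpr, db$ligand)
    RC <- getv(humanExpr, db$receptor)
    RS <- getv(mouseExpr, db$receptor)
    idx <- computeIndices(LC, LS, RC, RS)
    sc <- rbind(
        data.frame(ligand = db$ligand, receptor = db$receptor,
                   direction = "CS", X = idx$X_CS, Y = idx$Y_CS,
                   Z = idx$Z_CS, stringsAsFactors = FALSE),
        data.frame(ligand = db$ligand, receptor = db$receptor,
                   direction = "SC", X = idx$X_SC, Y = idx$Y_SC,
                   Z = idx$Z_SC, stringsAsFactors = FALSE))
    sc$defined <- !is.na(sc$X) & !is.na(sc$Y)
    sc$zone <- classifyZone(sc$X, sc$Y)
    rownames(sc) <- NULL
    new("InteractionProfile", scores = sc, nSamples = 1L)
}

#' Count strong interactions in a zone set
#'
#' Number of classified interactions whose zone lies in \code{zones} and
#' whose signal strength strictly exceeds \code{zMin}.
#'
#' @param profile An \linkS4class{InteractionProfile}.
#' @param zones Integer vector of zones (e.g. \code{1} for mutually
#'   dependent).
#' @param zMin Signal-strength threshold (strict >; default 10).
#' @param direction "CS" or "SC".
#' @return Integer count.
#' @export
countStrongByZone <- function(profile, zones = 1L, zMin = 10,
                              direction = c("CS", "SC")) {
    direction <- match.arg(direction)
    s <- scores(profile)
    sum(s$direction == direction & s$defined & s$zone %in% zones &
        s$Z > zMin)
}

#' Extract mutually dependent interactions with strong signals
#'
#' Candidate druggable interactions: ligand dependency > \code{xMin},
#' receptor dependency > \code{yMin} and signal strength > \code{zMin}
#' (all strict), reported for both directions and sorted by signal strength
#' descending.
#'
#' @param profile An \linkS4class{InteractionProfile}.
#' @param xMin,yMin,zMin Strict thresholds (defaults 0.75, 0.75, 50).
#' @return data.frame: ligand, receptor, direction, X, Y, Z, zone.
#' @export
extractMutuallyDependent <- function(profile, xMin = 0.75, yMin = 0.75,
                                     zMin = 50) {
    s <- scores(profile)
    keep <- s$defined & s$X > xMin & s$Y > yMin & s$Z > zMin
    out <- s[keep, c("ligand", "receptor", "direction", "X", "Y", "Z",
                     "zone")]
    out <- out[order(-out$Z, out$direction, out$ligand, out$receptor), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Average interaction profiles across samples
#'
#' Arithmetic mean of each index per interaction and direction; a dependency
#' index is averaged over the samples where it is defined
#' (pairwise-available mean), signal strength over all samples. Zones are
#' reclassified from the averaged indices. Sample order does not affect the
#' result.
#'
#' @param profiles List of \linkS4class{InteractionProfile} objects over the
#'   same interaction universe.
#' @return An \linkS4class{InteractionProfile}.
#' @export
averageProfiles <- function(profiles) {
    stopifnot(length(profiles) >= 1L)
    if (length(profiles) == 1L) return(profiles[[1L]])
    key <- function(s) paste(s$ligand, s$receptor, s$direction, sep = "\r")
    ref <- scores(profiles[[1L]])
    ref <- ref[order(key(ref)), , drop = FALSE]
    k0 <- key(ref)
    Xm <- Ym <- Zm <- matrix(NA_real_, nrow(ref), length(profiles))
    for (i in seq_along(profiles)) {
        s <- scores(profiles[[i]])
        if (!identical(sort(key(s)), k0))
            stop("profiles cover different interaction universes")
        s <- s[match(k0, key(s)), , drop = FALSE]
        Xm[, i] <- s$X; Ym[, i] <- s$Y; Zm[, i] <- s$Z
    }
    X <- rowMeans(Xm, na.rm = TRUE); X[is.nan(X)] <- NA_real_
    Y <- rowMeans(Ym, na.rm = TRUE); Y[is.nan(Y)] <- NA_real_
    Z <- rowMeans(Zm)
    out <- data.frame(ligand = ref$ligand, receptor = ref$receptor,
                      direction = ref$direction, X = X, Y = Y, Z = Z,
                      defined = !is.na(X) & !is.na(Y),
                      zone = classifyZone(X, Y), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    new("InteractionProfile", scores = out, nSamples = length(profiles))
}

#' Write an interaction profile as TSV
#'
#' @param profile An \linkS4class{InteractionProfile}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeInteractionProfile <- function(profile, path) {
    s <- scores(profile)
    s$X <- signif(s$X, 6); s$Y <- signif(s$Y, 6); s$Z <- signif(s$Z, 6)
    s$zone <- zoneLabel(s$direction, s$zone)
    write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' Export viewer scatter data as JSON
#'
#' Two scatter datasets (one per direction) with x = ligand dependency,
#' y = receptor dependency and circle radius proportional to log10 of the
#' signal strength, matching the interactive 2D viewer's input contract.
#' Undefined interactions are omitted.
#'
#' @param profile An \linkS4class{InteractionProfile}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeViewerJson <- function(profile, path) {
    s <- scores(profile)
    mk <- function(d) {
        sub <- s[s$direction == d & s$defined, , drop = FALSE]
        data.frame(ligand = sub$ligand, receptor = sub$receptor,
                   x = sub$X, y = sub$Y, z = sub$Z,
                   radius = log10(1 + sub$Z), stringsAsFactors = FALSE)
    }
    jsonlite::write_json(list(CS = mk("CS"), SC = mk("SC")), path,
                         digits = NA, auto_unbox = TRUE)
    invisible(path)
}
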