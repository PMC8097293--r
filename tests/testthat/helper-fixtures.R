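# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixGeneProfiles <- function() {
  if (is.null(.fix$profiles)) .fix$profiles <- coreGeneProfiles()
  .fix$profiles
}

fixSeeds <- function() {
  p <- fixGeneProfiles()
  Biostrings::AAStringSet(c(INT = as.character(p[["int"]]),
                            pPOLB = as.character(p[["ppolb"]])))
}

# small intact element reused across tests (minimum-size blueprint keeps
# alignment work down)
fixElement <- function() {
  if (is.null(.fix$element))
    .fix$element <- makeElement(
      elementBlueprint(totalLength = 12723L, tirLength = 300L),
      geneProfiles = fixGeneProfiles(), seed = 424242)
  .fix$element
}

# an implanted genome with that element and known truth
fixImplant <- function() {
  if (is.null(.fix$implant)) {
    g <- generateHostGenome(10000, 0.41, seed = 99)
    .fix$implant <- implantElement(g, fixElement(), site = 5000)
  }
  .fix$implant
}

mutateAt <- function(chars, positions) {
  for (pos in positions)
    chars[pos] <- setdiff(c("A", "C", "G", "T"),
                          chars[pos])[sample.int(3, 1)]
  chars
}

fix6TipHost <- function()
  ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")

fix6TipCodonTree <- function()
  ape::read.tree(text = paste0("(((t1:0.25,t2:0.25):0.25,t3:0.5):0.25,",
                               "(t4:0.5,(t5:0.25,t6:0.25):0.25):0.25);"))

randomPeptide <- function(n) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""),
               n, replace = TRUE), collapse = "")
}

randomDnaStr <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# enumerate labelled rooted binary trees by stepwise addition
enumerateRootedTrees <- function(tips) {
  if (length(tips) == 1)
    return(list(paste0(tips, ";")))
  if (length(tips) == 2)
    return(list(paste0("(", tips[1], ":1,", tips[2], ":1);")))
  grow <- function(newicks, tip) {
    out <- list()
    for (nw in newicks) {
      tr <- ape::read.tree(text = nw)
      nEdge <- nrow(tr$edge)
      for (e in seq_len(nEdge)) {
        t2 <- ape::bind.tree(tr, ape::read.tree(
          text = paste0("(", tip, ":1);")), where = tr$edge[e, 2],
          position = 0.5)
        out[[length(out) + 1L]] <- ape::write.tree(t2)
      }
      # also attach above the root
      t3 <- ape::read.tree(text = paste0(
        "(", sub(";$", "", nw), ":1,", tip, ":1);"))
      out[[length(out) + 1L]] <- ape::write.tree(t3)
    }
    unique(out)
  }
  cur <- list(paste0("(", tips[1], ":1,", tips[2], ":1);"))
  for (t in tips[-(1:2)]) cur <- grow(cur, t)
  lapply(unique(unlist(cur)), function(nw) {
    tr <- ape::read.tree(text = nw)
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  })
}
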