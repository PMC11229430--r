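library(fossilplace)

## toy congruent fixture: 8 backbone taxa + fossil identical to Charlie
taxa <- c("Alpha","Bravo","Charlie","Delta","Echo","Foxtrot","Golf","Hotel")
clades <- list(c("Alpha","Bravo"), c("Alpha","Bravo","Charlie"),
               c("Alpha","Bravo","Charlie","Delta"),
               c("Echo","Foxtrot"), c("Echo","Foxtrot","Golf"),
               c("Charlie"))
rows <- sapply(taxa, function(tx) {
  paste(unlist(lapply(clades, function(cl) rep(as.integer(tx %in% cl), 5))),
        collapse = "")
})
rows <- c(rows, Fossilis = rows[["Charlie"]])
cm <- char_matrix(rows)
write_nexus_matrix(cm, "inst/extdata/toy_matrix.nex")
bb <- "((((Alpha,Bravo),Charlie),Delta),(((Echo,Foxtrot),Golf),Hotel));"
writeLines(bb, "inst/extdata/toy_backbone.nwk")

## synthetic cleroid-like stand-in for the unavailable study matrix:
## 18-genus molecular backbone, fossil truly sister to Phloiophilus,
## 61 adult + 32 larval characters, fossil coded for exactly 31 adult
## characters and no larval ones.
true_nwk <- paste0(
 "((Byturus:0.25,Biphyllus:0.25):0.2,",
 "((Acanthocnemis:0.35,((Necrobia:0.15,Thanasimus:0.15):0.25,Phycosecis:0.4):0.1):0.1,",
 "((Rentonium:0.45,(Phloiophilus:0.15,Foveapeltis:0.15):0.15):0.1,",
 "(((Peltis:0.2,Calitys:0.2):0.15,Thymalus:0.3):0.1,",
 "(((Eronyxa:0.2,Lophocateres:0.2):0.1,(Grynocharis:0.2,Ancyrona:0.25):0.1):0.1,",
 "(Trogossita:0.15,(Tenebroides:0.15,Temnoscheila:0.15):0.1):0.15):0.1):0.1):0.1):0.1);")
true_tree <- parse_newick(true_nwk)
cfg <- sim_config(true_tree, n_characters = 93, n_states = 2,
                  missing_fraction = 30/61, designated_taxon = "Foveapeltis",
                  partitions = "adult=1-61,larval=62-93",
                  missing_partitions = "larval", seed = 20240708)
cm2 <- simulate_matrix(cfg)
cat("adult:", sum(cm2$partitions == "adult"),
    "larval:", sum(cm2$partitions == "larval"),
    "coded adult:", count_coded(cm2, "Foveapeltis", "adult"),
    "coded larval:", count_coded(cm2, "Foveapeltis", "larval"), "\n")
write_nexus_matrix(cm2, "inst/extdata/synthetic_cleroidea_matrix.nex")
pr <- prune_leaf(true_tree, "Foveapeltis")
write_newick(pr$tree, "inst/extdata/synthetic_cleroidea_backbone.nwk")
cat("true branch:", pr$branch, "\n")

ps <- exhaustive_placement(pr$tree, cm2, "Foveapeltis", weighting_scheme("implied", 12))
print(ps)
o <- ps$rows[order(ps$rows$iw_score), ]
print(head(o, 6))
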