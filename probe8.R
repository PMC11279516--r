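library(seosdd)
set.seed(13)
v <- c(round(rnorm(2700, 60, 8)), round(rnorm(5400, 180, 10)))
v <- as.integer(pmin(pmax(v, 0), 255))
img <- grayImage(matrix(v[1:(90*90)], 90, 90))
pr <- selectRange(findCandidates(slopeDifference(intensityHistogram(img))), "auto")
cat("cand:", candidates(pr), "\n")
tr <- binarySearchThreshold(img, pr, "dark", exhaustive=TRUE)
print(searchTrace(tr))
inv <- grayImage(255L - pixels(img))
prI <- selectRange(findCandidates(slopeDifference(intensityHistogram(inv))), "auto")
cat("candI:", candidates(prI), "\n")
trI <- binarySearchThreshold(inv, prI, "bright", exhaustive=TRUE)
print(searchTrace(trI))
cat("t:", selectedThreshold(tr), " mirror tI:", 255 - selectedThreshold(trI), "\n")
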