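lipid
adipo
lipo
vesicle
lipase
fatty
fats
abscisic
eicosanoid
leukotriene
docosanoid
octadecanoid
arachid
cholesterol
sterol
steryl
steroid
glucocorticoid
bile acid
phosphatidyl
ceramide
acetylcholine
gluconate
prenol
terpene
isoprene
isoprenoid
terpenoid
geranyl
quinones
hopanoid
glycerophospho
sphingo
ganglioside
acyltrehalose
acylaminosugar
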