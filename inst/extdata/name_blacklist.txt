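# Scientific-name recognizer blacklist, v1.
# Lowercased words that must never serve as the genus or epithet of a
# recognized name: Latin phrases common in scholarly prose, month names,
# and capitalized-English words that frequently start false-positive
# "Genus epithet"-shaped bigrams (journal-title and front-matter vocabulary).
# One word per line; "#" lines are comments. Extensible via the blacklist
# argument of find_scientific_names().
# -- Latin phrases --
in
situ
vitro
vivo
et
al
alia
sensu
lato
stricto
ad
hoc
a
priori
posteriori
per
se
de
novo
facto
via
versus
cetera
inter
intra
ex
post
pro
rata
sic
circa
confer
ibidem
idem
vide
supra
infra
# -- months --
january
february
march
april
may
june
july
august
september
october
november
december
# -- capitalized-English false-positive starters and journal vocabulary --
the
this
these
those
new
north
south
east
west
northern
southern
eastern
western
central
upper
lower
mount
lake
river
national
university
journal
press
bulletin
proceedings
transactions
annals
review
reviews
society
academy
institute
museum
sciences
science
nature
data
figure
figures
table
tables
appendix
supplementary
biological
biology
conservation
ecology
ecological
evolution
evolutionary
tropical
zoology
botany
research
international
global
american
european
royal
natural
history
methods
results
discussion
introduction
references
acknowledgements
abstract
keywords
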