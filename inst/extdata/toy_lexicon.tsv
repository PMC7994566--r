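word	synset_id
dog	animal.pet.dog
cat	animal.pet.cat
hamster	animal.pet.hamster
rabbit	animal.pet.rabbit
parrot	animal.pet.parrot
goldfish	animal.pet.goldfish
boxer	animal.pet.boxer
budgie	animal.pet.budgie
cow	animal.farm.cow
sheep	animal.farm.sheep
goat	animal.farm.goat
pig	animal.farm.pig
horse	animal.farm.horse
donkey	animal.farm.donkey
chicken	animal.farm.chicken
duck	animal.farm.duck
lion	animal.wild.lion
tiger	animal.wild.tiger
wolf	animal.wild.wolf
fox	animal.wild.fox
bear	animal.wild.bear
deer	animal.wild.deer
elephant	animal.wild.elephant
giraffe	animal.wild.giraffe
eagle	animal.bird.eagle
hawk	animal.bird.hawk
sparrow	animal.bird.sparrow
robin	animal.bird.robin
owl	animal.bird.owl
crow	animal.bird.crow
stork	animal.bird.stork
heron	animal.bird.heron
kiwi	animal.bird.kiwi
salmon	animal.fish.salmon
trout	animal.fish.trout
shark	animal.fish.shark
carp	animal.fish.carp
pike	animal.fish.pike
cod	animal.fish.cod
herring	animal.fish.herring
tuna	animal.fish.tuna
doctor	occupation.medical.doctor
nurse	occupation.medical.nurse
surgeon	occupation.medical.surgeon
dentist	occupation.medical.dentist
pharmacist	occupation.medical.pharmacist
midwife	occupation.medical.midwife
paramedic	occupation.medical.paramedic
therapist	occupation.medical.therapist
baker	occupation.trade.baker
butcher	occupation.trade.butcher
plumber	occupation.trade.plumber
carpenter	occupation.trade.carpenter
electrician	occupation.trade.electrician
mechanic	occupation.trade.mechanic
tailor	occupation.trade.tailor
mason	occupation.trade.mason
lawyer	occupation.office.lawyer
judge	occupation.office.judge
accountant	occupation.office.accountant
banker	occupation.office.banker
clerk	occupation.office.clerk
manager	occupation.office.manager
secretary	occupation.office.secretary
auditor	occupation.office.auditor
teacher	occupation.service.teacher
waiter	occupation.service.waiter
cook	occupation.service.cook
cleaner	occupation.service.cleaner
gardener	occupation.service.gardener
driver	occupation.service.driver
postman	occupation.service.postman
barber	occupation.service.barber
soccer	sport.ball.soccer
tennis	sport.ball.tennis
golf	sport.ball.golf
rugby	sport.ball.rugby
hockey	sport.ball.hockey
basketball	sport.ball.basketball
volleyball	sport.ball.volleyball
squash	sport.ball.squash
swimming	sport.water.swimming
rowing	sport.water.rowing
sailing	sport.water.sailing
surfing	sport.water.surfing
diving	sport.water.diving
kayaking	sport.water.kayaking
waterpolo	sport.water.waterpolo
snorkeling	sport.water.snorkeling
boxing	sport.combat.boxing
judo	sport.combat.judo
karate	sport.combat.karate
wrestling	sport.combat.wrestling
fencing	sport.combat.fencing
taekwondo	sport.combat.taekwondo
kickboxing	sport.combat.kickboxing
aikido	sport.combat.aikido
skiing	sport.winter.skiing
snowboarding	sport.winter.snowboarding
curling	sport.winter.curling
biathlon	sport.winter.biathlon
luge	sport.winter.luge
bobsled	sport.winter.bobsled
skeleton	sport.winter.skeleton
skating	sport.winter.skating
cherry	fruit.stone.cherry
plum	fruit.stone.plum
peach	fruit.stone.peach
apricot	fruit.stone.apricot
nectarine	fruit.stone.nectarine
mango	fruit.stone.mango
olive	fruit.stone.olive
date	fruit.stone.date
orange	fruit.citrus.orange
lemon	fruit.citrus.lemon
lime	fruit.citrus.lime
grapefruit	fruit.citrus.grapefruit
mandarin	fruit.citrus.mandarin
tangerine	fruit.citrus.tangerine
pomelo	fruit.citrus.pomelo
kumquat	fruit.citrus.kumquat
strawberry	fruit.berry.strawberry
raspberry	fruit.berry.raspberry
blueberry	fruit.berry.blueberry
cranberry	fruit.berry.cranberry
gooseberry	fruit.berry.gooseberry
currant	fruit.berry.currant
mulberry	fruit.berry.mulberry
elderberry	fruit.berry.elderberry
banana	fruit.tropical.banana
pineapple	fruit.tropical.pineapple
papaya	fruit.tropical.papaya
guava	fruit.tropical.guava
lychee	fruit.tropical.lychee
kiwi	fruit.tropical.kiwi
passionfruit	fruit.tropical.passionfruit
coconut	fruit.tropical.coconut
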