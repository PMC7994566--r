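id	gloss
entity	taxonomy root
animal	category: animal
animal.pet	subdomain: animal.pet
animal.pet.dog	sense of dog
animal.pet.cat	sense of cat
animal.pet.hamster	sense of hamster
animal.pet.rabbit	sense of rabbit
animal.pet.parrot	sense of parrot
animal.pet.goldfish	sense of goldfish
animal.pet.boxer	sense of boxer
animal.pet.budgie	sense of budgie
animal.farm	subdomain: animal.farm
animal.farm.cow	sense of cow
animal.farm.sheep	sense of sheep
animal.farm.goat	sense of goat
animal.farm.pig	sense of pig
animal.farm.horse	sense of horse
animal.farm.donkey	sense of donkey
animal.farm.chicken	sense of chicken
animal.farm.duck	sense of duck
animal.wild	subdomain: animal.wild
animal.wild.lion	sense of lion
animal.wild.tiger	sense of tiger
animal.wild.wolf	sense of wolf
animal.wild.fox	sense of fox
animal.wild.bear	sense of bear
animal.wild.deer	sense of deer
animal.wild.elephant	sense of elephant
animal.wild.giraffe	sense of giraffe
animal.bird	subdomain: animal.bird
animal.bird.eagle	sense of eagle
animal.bird.hawk	sense of hawk
animal.bird.sparrow	sense of sparrow
animal.bird.robin	sense of robin
animal.bird.owl	sense of owl
animal.bird.crow	sense of crow
animal.bird.stork	sense of stork
animal.bird.heron	sense of heron
animal.bird.kiwi	sense of kiwi
animal.fish	subdomain: animal.fish
animal.fish.salmon	sense of salmon
animal.fish.trout	sense of trout
animal.fish.shark	sense of shark
animal.fish.carp	sense of carp
animal.fish.pike	sense of pike
animal.fish.cod	sense of cod
animal.fish.herring	sense of herring
animal.fish.tuna	sense of tuna
occupation	category: occupation
occupation.medical	subdomain: occupation.medical
occupation.medical.doctor	sense of doctor
occupation.medical.nurse	sense of nurse
occupation.medical.surgeon	sense of surgeon
occupation.medical.dentist	sense of dentist
occupation.medical.pharmacist	sense of pharmacist
occupation.medical.midwife	sense of midwife
occupation.medical.paramedic	sense of paramedic
occupation.medical.therapist	sense of therapist
occupation.trade	subdomain: occupation.trade
occupation.trade.baker	sense of baker
occupation.trade.butcher	sense of butcher
occupation.trade.plumber	sense of plumber
occupation.trade.carpenter	sense of carpenter
occupation.trade.electrician	sense of electrician
occupation.trade.mechanic	sense of mechanic
occupation.trade.tailor	sense of tailor
occupation.trade.mason	sense of mason
occupation.office	subdomain: occupation.office
occupation.office.lawyer	sense of lawyer
occupation.office.judge	sense of judge
occupation.office.accountant	sense of accountant
occupation.office.banker	sense of banker
occupation.office.clerk	sense of clerk
occupation.office.manager	sense of manager
occupation.office.secretary	sense of secretary
occupation.office.auditor	sense of auditor
occupation.service	subdomain: occupation.service
occupation.service.teacher	sense of teacher
occupation.service.waiter	sense of waiter
occupation.service.cook	sense of cook
occupation.service.cleaner	sense of cleaner
occupation.service.gardener	sense of gardener
occupation.service.driver	sense of driver
occupation.service.postman	sense of postman
occupation.service.barber	sense of barber
sport	category: sport
sport.ball	subdomain: sport.ball
sport.ball.soccer	sense of soccer
sport.ball.tennis	sense of tennis
sport.ball.golf	sense of golf
sport.ball.rugby	sense of rugby
sport.ball.hockey	sense of hockey
sport.ball.basketball	sense of basketball
sport.ball.volleyball	sense of volleyball
sport.ball.squash	sense of squash
sport.water	subdomain: sport.water
sport.water.swimming	sense of swimming
sport.water.rowing	sense of rowing
sport.water.sailing	sense of sailing
sport.water.surfing	sense of surfing
sport.water.diving	sense of diving
sport.water.kayaking	sense of kayaking
sport.water.waterpolo	sense of waterpolo
sport.water.snorkeling	sense of snorkeling
sport.combat	subdomain: sport.combat
sport.combat.boxing	sense of boxing
sport.combat.judo	sense of judo
sport.combat.karate	sense of karate
sport.combat.wrestling	sense of wrestling
sport.combat.fencing	sense of fencing
sport.combat.taekwondo	sense of taekwondo
sport.combat.kickboxing	sense of kickboxing
sport.combat.aikido	sense of aikido
sport.winter	subdomain: sport.winter
sport.winter.skiing	sense of skiing
sport.winter.snowboarding	sense of snowboarding
sport.winter.curling	sense of curling
sport.winter.biathlon	sense of biathlon
sport.winter.luge	sense of luge
sport.winter.bobsled	sense of bobsled
sport.winter.skeleton	sense of skeleton
sport.winter.skating	sense of skating
fruit	category: fruit
fruit.stone	subdomain: fruit.stone
fruit.stone.cherry	sense of cherry
fruit.stone.plum	sense of plum
fruit.stone.peach	sense of peach
fruit.stone.apricot	sense of apricot
fruit.stone.nectarine	sense of nectarine
fruit.stone.mango	sense of mango
fruit.stone.olive	sense of olive
fruit.stone.date	sense of date
fruit.citrus	subdomain: fruit.citrus
fruit.citrus.orange	sense of orange
fruit.citrus.lemon	sense of lemon
fruit.citrus.lime	sense of lime
fruit.citrus.grapefruit	sense of grapefruit
fruit.citrus.mandarin	sense of mandarin
fruit.citrus.tangerine	sense of tangerine
fruit.citrus.pomelo	sense of pomelo
fruit.citrus.kumquat	sense of kumquat
fruit.berry	subdomain: fruit.berry
fruit.berry.strawberry	sense of strawberry
fruit.berry.raspberry	sense of raspberry
fruit.berry.blueberry	sense of blueberry
fruit.berry.cranberry	sense of cranberry
fruit.berry.gooseberry	sense of gooseberry
fruit.berry.currant	sense of currant
fruit.berry.mulberry	sense of mulberry
fruit.berry.elderberry	sense of elderberry
fruit.tropical	subdomain: fruit.tropical
fruit.tropical.banana	sense of banana
fruit.tropical.pineapple	sense of pineapple
fruit.tropical.papaya	sense of papaya
fruit.tropical.guava	sense of guava
fruit.tropical.lychee	sense of lychee
fruit.tropical.kiwi	sense of kiwi
fruit.tropical.passionfruit	sense of passionfruit
fruit.tropical.coconut	sense of coconut
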