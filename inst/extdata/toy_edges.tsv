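id1	id2
entity	animal
animal	animal.pet
animal.pet	animal.pet.dog
animal.pet	animal.pet.cat
animal.pet	animal.pet.hamster
animal.pet	animal.pet.rabbit
animal.pet	animal.pet.parrot
animal.pet	animal.pet.goldfish
animal.pet	animal.pet.boxer
animal.pet	animal.pet.budgie
animal	animal.farm
animal.farm	animal.farm.cow
animal.farm	animal.farm.sheep
animal.farm	animal.farm.goat
animal.farm	animal.farm.pig
animal.farm	animal.farm.horse
animal.farm	animal.farm.donkey
animal.farm	animal.farm.chicken
animal.farm	animal.farm.duck
animal	animal.wild
animal.wild	animal.wild.lion
animal.wild	animal.wild.tiger
animal.wild	animal.wild.wolf
animal.wild	animal.wild.fox
animal.wild	animal.wild.bear
animal.wild	animal.wild.deer
animal.wild	animal.wild.elephant
animal.wild	animal.wild.giraffe
animal	animal.bird
animal.bird	animal.bird.eagle
animal.bird	animal.bird.hawk
animal.bird	animal.bird.sparrow
animal.bird	animal.bird.robin
animal.bird	animal.bird.owl
animal.bird	animal.bird.crow
animal.bird	animal.bird.stork
animal.bird	animal.bird.heron
animal.bird	animal.bird.kiwi
animal	animal.fish
animal.fish	animal.fish.salmon
animal.fish	animal.fish.trout
animal.fish	animal.fish.shark
animal.fish	animal.fish.carp
animal.fish	animal.fish.pike
animal.fish	animal.fish.cod
animal.fish	animal.fish.herring
animal.fish	animal.fish.tuna
entity	occupation
occupation	occupation.medical
occupation.medical	occupation.medical.doctor
occupation.medical	occupation.medical.nurse
occupation.medical	occupation.medical.surgeon
occupation.medical	occupation.medical.dentist
occupation.medical	occupation.medical.pharmacist
occupation.medical	occupation.medical.midwife
occupation.medical	occupation.medical.paramedic
occupation.medical	occupation.medical.therapist
occupation	occupation.trade
occupation.trade	occupation.trade.baker
occupation.trade	occupation.trade.butcher
occupation.trade	occupation.trade.plumber
occupation.trade	occupation.trade.carpenter
occupation.trade	occupation.trade.electrician
occupation.trade	occupation.trade.mechanic
occupation.trade	occupation.trade.tailor
occupation.trade	occupation.trade.mason
occupation	occupation.office
occupation.office	occupation.office.lawyer
occupation.office	occupation.office.judge
occupation.office	occupation.office.accountant
occupation.office	occupation.office.banker
occupation.office	occupation.office.clerk
occupation.office	occupation.office.manager
occupation.office	occupation.office.secretary
occupation.office	occupation.office.auditor
occupation	occupation.service
occupation.service	occupation.service.teacher
occupation.service	occupation.service.waiter
occupation.service	occupation.service.cook
occupation.service	occupation.service.cleaner
occupation.service	occupation.service.gardener
occupation.service	occupation.service.driver
occupation.service	occupation.service.postman
occupation.service	occupation.service.barber
entity	sport
sport	sport.ball
sport.ball	sport.ball.soccer
sport.ball	sport.ball.tennis
sport.ball	sport.ball.golf
sport.ball	sport.ball.rugby
sport.ball	sport.ball.hockey
sport.ball	sport.ball.basketball
sport.ball	sport.ball.volleyball
sport.ball	sport.ball.squash
sport	sport.water
sport.water	sport.water.swimming
sport.water	sport.water.rowing
sport.water	sport.water.sailing
sport.water	sport.water.surfing
sport.water	sport.water.diving
sport.water	sport.water.kayaking
sport.water	sport.water.waterpolo
sport.water	sport.water.snorkeling
sport	sport.combat
sport.combat	sport.combat.boxing
sport.combat	sport.combat.judo
sport.combat	sport.combat.karate
sport.combat	sport.combat.wrestling
sport.combat	sport.combat.fencing
sport.combat	sport.combat.taekwondo
sport.combat	sport.combat.kickboxing
sport.combat	sport.combat.aikido
sport	sport.winter
sport.winter	sport.winter.skiing
sport.winter	sport.winter.snowboarding
sport.winter	sport.winter.curling
sport.winter	sport.winter.biathlon
sport.winter	sport.winter.luge
sport.winter	sport.winter.bobsled
sport.winter	sport.winter.skeleton
sport.winter	sport.winter.skating
entity	fruit
fruit	fruit.stone
fruit.stone	fruit.stone.cherry
fruit.stone	fruit.stone.plum
fruit.stone	fruit.stone.peach
fruit.stone	fruit.stone.apricot
fruit.stone	fruit.stone.nectarine
fruit.stone	fruit.stone.mango
fruit.stone	fruit.stone.olive
fruit.stone	fruit.stone.date
fruit	fruit.citrus
fruit.citrus	fruit.citrus.orange
fruit.citrus	fruit.citrus.lemon
fruit.citrus	fruit.citrus.lime
fruit.citrus	fruit.citrus.grapefruit
fruit.citrus	fruit.citrus.mandarin
fruit.citrus	fruit.citrus.tangerine
fruit.citrus	fruit.citrus.pomelo
fruit.citrus	fruit.citrus.kumquat
fruit	fruit.berry
fruit.berry	fruit.berry.strawberry
fruit.berry	fruit.berry.raspberry
fruit.berry	fruit.berry.blueberry
fruit.berry	fruit.berry.cranberry
fruit.berry	fruit.berry.gooseberry
fruit.berry	fruit.berry.currant
fruit.berry	fruit.berry.mulberry
fruit.berry	fruit.berry.elderberry
fruit	fruit.tropical
fruit.tropical	fruit.tropical.banana
fruit.tropical	fruit.tropical.pineapple
fruit.tropical	fruit.tropical.papaya
fruit.tropical	fruit.tropical.guava
fruit.tropical	fruit.tropical.lychee
fruit.tropical	fruit.tropical.kiwi
fruit.tropical	fruit.tropical.passionfruit
fruit.tropical	fruit.tropical.coconut
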