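# Biomedical character knowledge table
# columns: char <TAB> primary_radical <TAB> readings (;-separated) <TAB> ids
# Covers the worked biomedical examples (illness/tuberculosis/pain/liver/
# chest/brain; stomach/heart/harm; the nested 徒 case) plus the transliterated
# drug/disease names, together with every component the nested-IDS check
# needs. Components deliberately absent (龰, 丷) stay unknown leaves.
病	疒	bìng	⿸疒丙
痨	疒	láo	⿸疒劳
痛	疒	tòng	⿸疒甬
肝	月	gān	⿰月干
胸	月	xiōng	⿰月匈
脑	月	nǎo	⿰月㐫
胃	月	wèi	⿱田月
心	心	xīn	心
害	宀	hài	⿳宀丰口
徒	彳	tú	⿰彳走
走	走	zǒu	⿱土龰
土	土	tǔ	土
疒	疒	nè	疒
丙	一	bǐng	丙
劳	力	láo	劳
甬	用	yǒng	甬
月	月	yuè	月
干	干	gān;gàn	干
匈	勹	xiōng	匈
㐫	凵	xiōng	⿱丷凶
凶	凵	xiōng	凶
田	田	tián	田
宀	宀	mián	宀
丰	丨	fēng	丰
口	口	kǒu	口
彳	彳	chì	彳
症	疒	zhèng	⿸疒正
正	一	zhèng	正
阿	阝	ā	阿
司	口	sī	司
匹	匸	pǐ	匹
林	木	lín	⿰木木
木	木	mù	木
帕	巾	pà	⿰巾白
巾	巾	jīn	巾
白	白	bái	白
金	金	jīn	金
森	木	sēn	⿱木⿰木木
氏	氏	shì	氏
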