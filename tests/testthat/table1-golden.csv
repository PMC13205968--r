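qid,position,text,score
Q1,1,"I’m considering pregnancy",NA
Q1,2,"I’m currently pregnant",NA
Q1,3,"I have a baby or young children at home",NA
Q3,1,"Never, or only by passing smokers outdoors in public places",10
Q3,2,"Sometimes, I’m around smokers a few times a week, mostly outdoors",6
Q3,3,"Frequently, someone in my home smokes",3
Q3,4,"Daily, I smoke",1
Q4,1,"Almost never, I only use “green” products with minimal chemical ingredients",9
Q4,2,"Weekly, or a few times a month",6
Q4,3,"Daily, or a few times a week",2
Q5,1,"Never or rarely",9
Q5,2,"Sometimes, or I’m not sure",5
Q5,3,"Regularly, monthly or more frequently",1
Q6,1,"Almost never",10
Q6,2,"A few times a month",7
Q6,3,"A few times a week",3
Q6,4,"Daily",1
Q7,1,"Always, or at least the ones recommended by DirtyDozen",9
Q7,2,"Sometimes",5
Q7,3,"Never, I buy what’s available or cheapest",2
Q8,1,"Less than 10",9
Q8,2,"10–18",5
Q8,3,">18",1
Q9,1,"All the time, for all the products I can",NA
Q9,2,"Sometimes",NA
Q9,3,"Never",NA
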